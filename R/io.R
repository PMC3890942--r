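#' Write or read a trial log
#'
#' Trial logs are plain TSV with a `#`-prefixed header block carrying the
#' environment configuration, the static-object positions, the shadow-offset
#' sign convention, the seed, and any metadata, followed by one row per step:
#' `step`, `time_ms`, `p1_pos`, `p2_pos`, `p1_stim`, `p2_stim`, `p1_click`,
#' `p2_click` (stimulation and clicks as 0/1; a click column is 1 exactly at
#' the step of that player's retained click). Positions are serialized at
#' full double precision so that `read_trial_log(write_trial_log(rec))`
#' reproduces the recording exactly.
#'
#' @param rec A `trial_recording`.
#' @param path File path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns a `trial_recording`.
#' @export
write_trial_log <- function(rec, path) {
  cfg <- rec$cfg
  hdr <- c(
    unclass(cfg),
    list(
      static_pos_1 = sprintf("%.17g", rec$static_pos[1]),
      static_pos_2 = sprintf("%.17g", rec$static_pos[2]),
      shadow_sign = rec$meta$shadow_sign
    ),
    rec$meta[setdiff(names(rec$meta), "shadow_sign")]
  )
  hdr <- hdr[!vapply(hdr, is.null, logical(1))]
  header_lines <- sprintf("# %s\t%s", names(hdr), vapply(hdr, format, character(1)))
  n <- nrow(rec$steps)
  click1 <- integer(n)
  click2 <- integer(n)
  for (j in seq_len(nrow(rec$clicks))) {
    i <- rec$clicks$step[j] + 1L
    if (rec$clicks$player[j] == 1) click1[i] <- 1L else click2[i] <- 1L
  }
  body <- sprintf(
    "%d\t%s\t%s\t%s\t%d\t%d\t%d\t%d",
    rec$steps$step, sprintf("%.10g", rec$steps$time_ms),
    sprintf("%.17g", rec$steps$pos1), sprintf("%.17g", rec$steps$pos2),
    as.integer(rec$steps$stim1), as.integer(rec$steps$stim2),
    click1, click2
  )
  writeLines(
    c(
      header_lines,
      "step\ttime_ms\tp1_pos\tp2_pos\tp1_stim\tp2_stim\tp1_click\tp2_click",
      body
    ),
    path
  )
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr_lines, "\t", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("Malformed header line: ", hdr_lines[which(bad)[1]], call. = FALSE)
  }
  hdr <- stats::setNames(
    lapply(kv, function(x) x[2]),
    vapply(kv, function(x) x[1], character(1))
  )
  cfg_keys <- names(formals(env_config))
  cfg_vals <- lapply(hdr[intersect(names(hdr), cfg_keys)], as.numeric)
  if (length(cfg_vals) == 0) {
    stop("Malformed header: no configuration keys found.", call. = FALSE)
  }
  cfg <- do.call(env_config, cfg_vals)

  tbl <- utils::read.delim(
    textConnection(lines[!is_hdr]),
    sep = "\t", header = TRUE,
    colClasses = c(
      "integer", "numeric", "numeric", "numeric",
      "integer", "integer", "integer", "integer"
    )
  )
  required <- c(
    "step", "time_ms", "p1_pos", "p2_pos", "p1_stim", "p2_stim",
    "p1_click", "p2_click"
  )
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("Trial log is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(diff(tbl$step) != 1L) || tbl$step[1] != 0L) {
    stop("Trial log steps must be 0-based and strictly consecutive.",
      call. = FALSE
    )
  }
  L <- cfg$space_length
  pos_cols <- c(tbl$p1_pos, tbl$p2_pos)
  if (any(pos_cols < 0 | pos_cols >= L)) {
    stop(sprintf("Position outside [0, %g) in trial log.", L), call. = FALSE)
  }
  static_pos <- as.numeric(c(hdr$static_pos_1, hdr$static_pos_2))
  if (length(static_pos) != 2 || any(is.na(static_pos))) {
    stop("Malformed header: static_pos_1 / static_pos_2 required.",
      call. = FALSE
    )
  }
  meta_keys <- setdiff(names(hdr), c(cfg_keys, "static_pos_1", "static_pos_2"))
  meta <- lapply(hdr[meta_keys], utils::type.convert, as.is = TRUE)
  if (is.null(meta$shadow_sign)) meta$shadow_sign <- 1

  clicks <- tibble::tibble(
    player = c(
      rep(1L, sum(tbl$p1_click == 1L)),
      rep(2L, sum(tbl$p2_click == 1L))
    ),
    step = c(
      tbl$step[tbl$p1_click == 1L],
      tbl$step[tbl$p2_click == 1L]
    )
  )
  clicks$time_ms <- clicks$step * cfg$sample_period

  rec <- structure(
    list(
      cfg = cfg,
      steps = tibble::tibble(
        step = tbl$step, time_ms = tbl$time_ms,
        pos1 = tbl$p1_pos, pos2 = tbl$p2_pos,
        stim1 = tbl$p1_stim == 1L, stim2 = tbl$p2_stim == 1L
      ),
      static_pos = static_pos,
      clicks = clicks,
      meta = meta
    ),
    class = "trial_recording"
  )
  for (p in 1:2) {
    ov <- overlap_channels(rec, p)
    recomputed <- ov$avatar | ov$shadow | ov$static
    if (!identical(recomputed, player_stim(rec, p))) {
      stop(sprintf(
        "Recorded stimulation of player %d is inconsistent with positions.", p
      ), call. = FALSE)
    }
  }
  rec
}
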