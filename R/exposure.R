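#' Inhalation exposure schedules
#'
#' An exposure schedule is an ordered set of non-overlapping square-wave
#' exposure episodes (start hour, end hour, concentration in ppm) together
#' with the sampling times at which adducts are read out. Exposure switches
#' on and off instantaneously (no chamber ramp); episodes are half-open
#' intervals \code{[start, end)}.
#'
#' @param episodes a data frame with columns \code{start_h}, \code{end_h},
#'   \code{ppm}.
#' @param sampling_times numeric vector of sampling times (h).
#' @param horizon simulation horizon (h); defaults to the latest episode end
#'   or sampling time.
#' @param label schedule label carried into trajectories for provenance.
#' @return an object of class \code{exposure_schedule}.
#' @export
exposure_schedule <- function(episodes, sampling_times = numeric(),
                              horizon = NULL, label = "custom") {
  if (is.null(episodes) || nrow(as.data.frame(episodes)) == 0L) {
    episodes <- data.frame(start_h = numeric(), end_h = numeric(),
                           ppm = numeric())
  }
  episodes <- as.data.frame(episodes)
  stopifnot(all(c("start_h", "end_h", "ppm") %in% names(episodes)))
  episodes <- episodes[order(episodes$start_h), , drop = FALSE]
  rownames(episodes) <- NULL
  if (nrow(episodes)) {
    if (any(episodes$end_h <= episodes$start_h))
      stop("each episode must have end_h > start_h", call. = FALSE)
    if (any(episodes$ppm < 0))
      stop("episode ppm must be non-negative", call. = FALSE)
    if (any(episodes$start_h < 0))
      stop("episodes must start at or after t = 0", call. = FALSE)
    if (nrow(episodes) > 1L &&
        any(episodes$start_h[-1L] < episodes$end_h[-nrow(episodes)]))
      stop("episodes must be non-overlapping and strictly ordered",
           call. = FALSE)
  }
  sampling_times <- sort(unique(as.numeric(sampling_times)))
  if (length(sampling_times) && any(sampling_times < 0))
    stop("sampling times must be non-negative", call. = FALSE)
  if (is.null(horizon))
    horizon <- max(c(episodes$end_h, sampling_times, 0))
  if (length(sampling_times) && any(sampling_times > horizon))
    stop("sampling times must lie within the schedule horizon", call. = FALSE)
  structure(list(label = label, episodes = episodes,
                 sampling_times = sampling_times,
                 horizon = as.numeric(horizon)),
            class = "exposure_schedule")
}

#' @export
print.exposure_schedule <- function(x, ...) {
  cat("<exposure_schedule> '", x$label, "': ", nrow(x$episodes),
      " episode(s), horizon ", x$horizon, " h\n", sep = "")
  if (nrow(x$episodes) <= 8L) print(x$episodes)
  else {
    print(utils::head(x$episodes, 3L))
    cat("... (", nrow(x$episodes) - 3L, " more)\n", sep = "")
  }
  cat("sampling times (h):", paste(x$sampling_times, collapse = ", "), "\n")
  invisible(x)
}

#' Instantaneous exposure concentration
#'
#' Evaluates the square-wave exposure concentration at time \code{t}.
#' Episodes are half-open \code{[start, end)}; between episodes the
#' concentration is zero.
#'
#' @param schedule an [exposure_schedule()].
#' @param t time or vector of times (h), within \code{[0, horizon]}.
#' @return ppm at each time.
#' @examples
#' s <- single_exposure(2)
#' ppm_at(s, 3)    # 2
#' ppm_at(s, 6.5)  # 0
#' @export
ppm_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  t <- as.numeric(t)
  if (any(t < 0 | t > schedule$horizon))
    stop("t outside the schedule horizon [0, ", schedule$horizon, "]",
         call. = FALSE)
  ep <- schedule$episodes
  out <- numeric(length(t))
  if (nrow(ep)) {
    idx <- findInterval(t, ep$start_h)
    hit <- idx >= 1L & t < ep$end_h[pmax(idx, 1L)]
    out[hit] <- ep$ppm[idx[hit]]
  }
  out
}

#' Single 6-h exposure protocol
#'
#' One exposure episode starting at t = 0, sampled (by default) 1 h after the
#' end of a 6-h exposure, i.e. 7 h from the start — the design of the
#' single-exposure DG monoadduct studies.
#'
#' @param ppm exposure concentration (>= 0).
#' @param duration_h exposure duration (h), default 6.
#' @param sample_at_h sampling time from exposure start (h), default 7.
#' @return an [exposure_schedule()].
#' @export
single_exposure <- function(ppm, duration_h = 6, sample_at_h = 7) {
  if (!is.numeric(ppm) || length(ppm) != 1L || ppm < 0)
    stop("ppm must be a single non-negative number", call. = FALSE)
  if (duration_h <= 0) stop("duration_h must be positive", call. = FALSE)
  episodes <- if (ppm > 0)
    data.frame(start_h = 0, end_h = duration_h, ppm = ppm)
  else
    data.frame(start_h = numeric(), end_h = numeric(), ppm = numeric())
  exposure_schedule(episodes, sampling_times = sample_at_h,
                    horizon = max(duration_h, sample_at_h),
                    label = sprintf("single_%gppm", ppm))
}

#' Repeated daily exposure protocol
#'
#' \code{n_exposure_days} consecutive exposure days of
#' \code{hours_per_day} h each. With the default origin offset the first
#' episode begins at t = 24 h (t = 0 sits one day before the first exposure),
#' so exposure day n occupies \code{[24 n, 24 n + hours_per_day)}; this
#' reproduces the printed sampling times of the 28-day time-course study
#' (e.g. day 7 sampled at 24*7 + 7 = 175 h). During-exposure samples are
#' taken \code{sample_offset_h} after the start of each day in
#' \code{sample_days}; post-exposure samples are offsets from the end of the
#' last episode.
#'
#' @param ppm exposure concentration.
#' @param hours_per_day exposure hours per day, default 6.
#' @param n_exposure_days number of consecutive exposure days (>= 1).
#' @param first_start_h start of the first episode (h), default 24; use 0 to
#'   start exposing at t = 0.
#' @param sample_days integer vector of exposure days (1-based) sampled
#'   during the exposure period; default the final day. Use
#'   \code{integer(0)} for none.
#' @param sample_offset_h sampling offset from the start of a sampled day
#'   (h), default 7 (1 h after a 6-h exposure ends).
#' @param post_samples_h offsets (h) from the end of the last episode for
#'   post-exposure samples.
#' @return an [exposure_schedule()].
#' @examples
#' # 28-day time-course design: samples at 175, 343, 511, 679, 684, ... h
#' s <- daily_schedule(2, n_exposure_days = 28, sample_days = c(7, 14, 21, 28),
#'                     post_samples_h = c(6, 24, 72, 168))
#' s$sampling_times
#' @export
daily_schedule <- function(ppm, hours_per_day = 6, n_exposure_days,
                           first_start_h = 24,
                           sample_days = n_exposure_days,
                           sample_offset_h = 7,
                           post_samples_h = NULL) {
  if (!is.numeric(ppm) || length(ppm) != 1L || ppm < 0)
    stop("ppm must be a single non-negative number", call. = FALSE)
  n_exposure_days <- as.integer(n_exposure_days)
  if (n_exposure_days < 1L) stop("n_exposure_days must be >= 1", call. = FALSE)
  if (hours_per_day <= 0 || hours_per_day > 24)
    stop("hours_per_day must be in (0, 24]", call. = FALSE)
  starts <- first_start_h + 24 * (seq_len(n_exposure_days) - 1L)
  episodes <- data.frame(start_h = starts, end_h = starts + hours_per_day,
                         ppm = ppm)
  if (ppm == 0)
    episodes <- episodes[0, , drop = FALSE]
  last_end <- first_start_h + 24 * (n_exposure_days - 1L) + hours_per_day
  sampling <- numeric()
  if (length(sample_days)) {
    sample_days <- as.integer(sample_days)
    if (any(sample_days < 1L | sample_days > n_exposure_days))
      stop("sample_days must lie in 1..n_exposure_days", call. = FALSE)
    sampling <- first_start_h + 24 * (sample_days - 1L) + sample_offset_h
  }
  if (length(post_samples_h))
    sampling <- c(sampling, last_end + post_samples_h)
  exposure_schedule(episodes, sampling_times = sampling,
                    horizon = max(c(last_end, sampling)),
                    label = sprintf("daily_%gppm_%dd", ppm, n_exposure_days))
}

#' Chronic 11-week + 4-day exposure protocol
#'
#' The chronic DPX study design: 6 h/day, 5 days/week for 11 weeks and
#' 4 days, then a final 3-h exposure on the 5th day of the 12th week with
#' sacrifice immediately after. Calendar day d (1-based) starts at
#' \code{24 (d - 1)} h, so the final 3-h episode runs over
#' \code{[1944, 1947)} and the sampling time is 1947 h, matching the printed
#' design (1947 = 24*81 + 3). 59 six-hour exposure days precede the final
#' 3-h day (357 exposed hours in total).
#'
#' @param ppm exposure concentration.
#' @return an [exposure_schedule()].
#' @examples
#' s <- casanova_schedule(15.8)
#' s$sampling_times  # 1947
#' nrow(s$episodes)  # 60
#' @export
casanova_schedule <- function(ppm) {
  if (!is.numeric(ppm) || length(ppm) != 1L || ppm < 0)
    stop("ppm must be a single non-negative number", call. = FALSE)
  days <- 1:81
  dow <- (days - 1L) %% 7L + 1L            # day of week, 1..7
  exp_days <- days[dow <= 5L]              # 5 exposure days per week; 59 days
  starts <- 24 * (exp_days - 1L)
  episodes <- data.frame(start_h = starts, end_h = starts + 6, ppm = ppm)
  # final day: 5th day of week 12, 3-h exposure, sacrifice immediately
  episodes <- rbind(episodes,
                    data.frame(start_h = 24 * 81, end_h = 24 * 81 + 3,
                               ppm = ppm))
  if (ppm == 0) episodes <- episodes[0, , drop = FALSE]
  exposure_schedule(episodes, sampling_times = 24 * 81 + 3,
                    horizon = 24 * 81 + 3,
                    label = sprintf("casanova_%gppm", ppm))
}

#' Low-concentration 28-day protocol
#'
#' The low-dose non-detect study design: 28 consecutive days of 6 h/day
#' exposure starting at t = 0, with adducts read out at 672 h (18 h after the
#' end of the last exposure).
#'
#' @param ppm exposure concentration, default 0.3.
#' @return an [exposure_schedule()].
#' @export
leng_schedule <- function(ppm = 0.3) {
  daily_schedule(ppm, n_exposure_days = 28, first_start_h = 0,
                 sample_days = integer(0), post_samples_h = 18)
}

#' Serialize / deserialize an exposure schedule
#'
#' Writes the episode table and sampling times as plain delimited text;
#' \code{read_schedule()} restores the schedule.
#'
#' @param schedule an [exposure_schedule()].
#' @param path file path.
#' @return \code{write_schedule}: the path, invisibly;
#'   \code{read_schedule}: an [exposure_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label: ", schedule$label),
               paste0("# horizon_h: ", format(schedule$horizon, digits = 17)),
               paste0("# sampling_times_h: ",
                      paste(format(schedule$sampling_times, digits = 17),
                            collapse = ","))), con)
  utils::write.table(schedule$episodes, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^# ", key, ": "), "", m[1L])
  }
  label <- get("label")
  horizon <- as.numeric(get("horizon_h"))
  st <- get("sampling_times_h")
  sampling <- if (is.null(st) || !nzchar(st)) numeric()
              else as.numeric(strsplit(st, ",")[[1L]])
  episodes <- utils::read.table(textConnection(lines[!grepl("^#", lines)]),
                                header = TRUE, sep = "\t")
  exposure_schedule(episodes, sampling_times = sampling, horizon = horizon,
                    label = if (is.null(label)) "custom" else label)
}
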