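# Reading, validating and assembling trap-catch and environment tables.
#
# All inputs are long-format CSV: one row per trap per session (counts), one
# row per fish (lengths), one row per logger reading, one row per spot
# measurement phase. Long layout keeps every join explicit and validatable.

CATCH_COLS <- c("site_id", "week", "time_of_day", "trap_location",
                "n_total", "n_red_males")
LENGTH_COLS <- c("site_id", "week", "trap_location", "fish_index",
                 "body_length_mm")
LOGGER_COLS <- c("site_id", "week", "trap_location", "timestamp",
                 "temperature_c", "light_lumft2")
SPOT_COLS <- c("site_id", "week", "trap_location", "phase",
               "turbidity_ntu", "do_mgl")

# base as.POSIXct silently degrades "2021-05-03T10:00:00" to a date, so the
# ISO-8601 'T' separator must be handled explicitly
parse_iso_time <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
}

read_table_arg <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("cannot read ", what, ": file not found: ", x)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    as.data.frame(x, stringsAsFactors = FALSE)
  } else {
    stop(what, " must be a CSV path or a data.frame")
  }
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_validation(what, " is missing required column(s): ",
                    paste(missing, collapse = ", "))
  df
}

#' Read and assemble trap-catch sessions
#'
#' Reads the long-format catch table (one row per trap per sampling session)
#' and, optionally, the per-fish body-length table, validates both against the
#' schema, and assembles them into sampling sessions: one simultaneous
#' deployment of `n_traps` traps at one site.
#'
#' @param catches CSV path or data.frame with columns `site_id, week,
#'   time_of_day, trap_location, n_total, n_red_males`.
#' @param lengths Optional CSV path or data.frame with columns `site_id, week,
#'   trap_location, fish_index, body_length_mm`; lengths are attached to traps
#'   by the `(site_id, week, trap_location)` join.
#' @param n_traps Expected number of traps per session (default 5). Sessions
#'   with fewer traps are kept and reported via the `incomplete` attribute.
#' @return An object of class `trap_sessions`: a list of sessions, each a list
#'   with `site_id`, `week`, `time_of_day`, `traps` (data.frame of
#'   `trap_location, n_total, n_red_males, n_measured`), `lengths` (list of
#'   numeric vectors, one per trap, in `traps` order) and `session_total`.
#' @examples
#' dat <- generate_dataset(paper_scale_preset(seed = 1))
#' sessions <- read_catch_table(dat$catches, dat$lengths)
#' sessions[[1]]
#' @export
read_catch_table <- function(catches, lengths = NULL, n_traps = 5L) {
  cat_df <- check_cols(read_table_arg(catches, "catches"), CATCH_COLS, "catches")
  cat_df$week <- as.integer(cat_df$week)
  cat_df$trap_location <- as.integer(cat_df$trap_location)

  if (nrow(cat_df)) {
    if (any(!cat_df$time_of_day %in% c("am", "pm")))
      stop_validation("time_of_day must be 'am' or 'pm'")
    bad_loc <- !is.finite(cat_df$trap_location) |
      cat_df$trap_location < 1L | cat_df$trap_location > n_traps
    if (any(bad_loc))
      stop_validation("trap_location out of range 1..", n_traps, " in row(s) ",
                      paste(which(bad_loc), collapse = ", "))
    if (any(cat_df$n_total < 0) || any(cat_df$n_red_males < 0))
      stop_validation("counts must be non-negative")
    if (any(cat_df$n_red_males > cat_df$n_total))
      stop_validation("n_red_males exceeds n_total in row(s) ",
                      paste(which(cat_df$n_red_males > cat_df$n_total),
                            collapse = ", "))
    key <- paste(cat_df$site_id, cat_df$week, cat_df$trap_location)
    if (anyDuplicated(key))
      stop_validation("duplicate (site_id, week, trap_location) rows: ",
                      paste(unique(key[duplicated(key)]), collapse = "; "))
  }

  len_df <- NULL
  if (!is.null(lengths)) {
    len_df <- check_cols(read_table_arg(lengths, "lengths"), LENGTH_COLS,
                         "lengths")
    len_df$week <- as.integer(len_df$week)
    len_df$trap_location <- as.integer(len_df$trap_location)
    if (nrow(len_df) && any(!is.finite(len_df$body_length_mm) |
                            len_df$body_length_mm <= 0))
      stop_validation("body_length_mm must be positive and finite")
  }

  skey <- unique(cat_df[, c("site_id", "week")])
  skey <- skey[order(skey$site_id, skey$week), , drop = FALSE]
  sessions <- vector("list", nrow(skey))
  incomplete <- character(0)

  for (i in seq_len(nrow(skey))) {
    rows <- cat_df[cat_df$site_id == skey$site_id[i] &
                     cat_df$week == skey$week[i], , drop = FALSE]
    rows <- rows[order(rows$trap_location), , drop = FALSE]
    if (length(unique(rows$time_of_day)) > 1L)
      stop_validation("session (", skey$site_id[i], ", week ", skey$week[i],
                      ") mixes am and pm rows")
    len_list <- rep(list(numeric(0)), nrow(rows))
    if (!is.null(len_df)) {
      for (j in seq_len(nrow(rows))) {
        lj <- len_df$body_length_mm[
          len_df$site_id == rows$site_id[j] & len_df$week == rows$week[j] &
            len_df$trap_location == rows$trap_location[j]]
        if (length(lj) > rows$n_total[j])
          stop_validation("more measured lengths (", length(lj),
                          ") than fish caught (", rows$n_total[j], ") at (",
                          rows$site_id[j], ", week ", rows$week[j], ", trap ",
                          rows$trap_location[j], ")")
        len_list[[j]] <- as.numeric(lj)
      }
    }
    traps <- data.frame(trap_location = rows$trap_location,
                        n_total = as.integer(rows$n_total),
                        n_red_males = as.integer(rows$n_red_males),
                        n_measured = vapply(len_list, length, integer(1)))
    if (nrow(traps) < n_traps)
      incomplete <- c(incomplete,
                      sprintf("(%s, week %d): %d of %d traps",
                              skey$site_id[i], skey$week[i], nrow(traps),
                              n_traps))
    sessions[[i]] <- structure(
      list(site_id = skey$site_id[i], week = skey$week[i],
           time_of_day = rows$time_of_day[1], traps = traps,
           lengths = len_list, session_total = sum(traps$n_total)),
      class = "session_catch")
  }
  if (length(incomplete))
    warning("incomplete sessions (fewer than ", n_traps, " traps): ",
            paste(incomplete, collapse = "; "), call. = FALSE)
  structure(sessions, class = "trap_sessions",
            incomplete = incomplete, n_traps = n_traps)
}

#' @export
print.session_catch <- function(x, ...) {
  cat(sprintf("Sampling session: site %s, week %d (%s)\n", x$site_id, x$week,
              x$time_of_day))
  cat(sprintf("  %d fish across %d traps; %d measured for length\n",
              x$session_total, nrow(x$traps), sum(x$traps$n_measured)))
  print(x$traps, row.names = FALSE)
  invisible(x)
}

#' @export
print.trap_sessions <- function(x, ...) {
  cat(sprintf("<trap_sessions> %d sessions, %d sites, weeks %s\n", length(x),
              length(unique(vapply(x, `[[`, "", "site_id"))),
              paste(range(vapply(x, `[[`, 0L, "week")), collapse = "-")))
  invisible(x)
}

#' Flatten sessions back to the long catch table
#'
#' @param x A `trap_sessions` object.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return A data.frame with the `catches.csv` schema.
#' @export
as.data.frame.trap_sessions <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  do.call(rbind, lapply(unclass(x), function(s)
    data.frame(site_id = s$site_id, week = s$week,
               time_of_day = s$time_of_day, trap_location = s$traps$trap_location,
               n_total = s$traps$n_total, n_red_males = s$traps$n_red_males)))
}

#' Extract the per-fish length table from sessions
#'
#' @param sessions A `trap_sessions` object.
#' @return A data.frame with the `lengths.csv` schema.
#' @export
session_lengths <- function(sessions) {
  out <- lapply(unclass(sessions), function(s) {
    n <- vapply(s$lengths, length, integer(1))
    if (!sum(n)) return(NULL)
    data.frame(site_id = s$site_id, week = s$week,
               trap_location = rep(s$traps$trap_location, n),
               fish_index = unlist(lapply(n[n > 0], seq_len)),
               body_length_mm = unlist(s$lengths))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(site_id = character(0), week = integer(0),
                      trap_location = integer(0), fish_index = integer(0),
                      body_length_mm = numeric(0))
  out
}

#' Write sessions to the catch and length CSV schemas
#'
#' @param sessions A `trap_sessions` object.
#' @param catches_path,lengths_path Output CSV paths; `lengths_path = NULL`
#'   skips the length table.
#' @return Invisibly, the paths written.
#' @export
write_catch_tables <- function(sessions, catches_path, lengths_path = NULL) {
  utils::write.csv(as.data.frame(sessions), catches_path, row.names = FALSE)
  if (!is.null(lengths_path))
    utils::write.csv(session_lengths(sessions), lengths_path,
                     row.names = FALSE)
  invisible(c(catches_path, lengths_path))
}

#' Read per-trap environment series and spot measurements
#'
#' Assembles one record per (site, week, trap) from the one-minute logger
#' table (temperature, light intensity) and the start/end spot-measurement
#' table (turbidity, dissolved oxygen). The sampling-session window is
#' inferred per session from the earliest and latest logger timestamp across
#' its traps unless supplied; a trap series lying entirely outside its
#' session's window is dropped with a warning.
#'
#' @param loggers CSV path or data.frame with columns `site_id, week,
#'   trap_location, timestamp, temperature_c, light_lumft2` (ISO-8601
#'   timestamps, ~1-minute cadence over the 2-h session).
#' @param spot Optional CSV path or data.frame with columns `site_id, week,
#'   trap_location, phase` (`start`/`end`), `turbidity_ntu, do_mgl`.
#' @param window Optional data.frame `site_id, week, window_start, window_end`
#'   overriding the inferred session windows.
#' @return An object of class `env_series`: a list of records, each with
#'   `site_id`, `week`, `trap_location`, `series` (data.frame of timestamp,
#'   temperature_c, light_lumft2), `turbidity` and `do` (named start/end
#'   vectors, possibly NA), and `flags` (character).
#' @export
read_env_tables <- function(loggers, spot = NULL, window = NULL) {
  log_df <- check_cols(read_table_arg(loggers, "env_loggers"), LOGGER_COLS,
                       "env_loggers")
  if (!nrow(log_df)) {
    warning("empty logger table: no environment series read", call. = FALSE)
    return(structure(list(), class = "env_series"))
  }
  log_df$week <- as.integer(log_df$week)
  log_df$trap_location <- as.integer(log_df$trap_location)
  log_df$timestamp <- parse_iso_time(log_df$timestamp)
  if (anyNA(log_df$timestamp))
    stop_validation("unparseable ISO-8601 timestamp in logger table")
  if (any(!is.finite(log_df$temperature_c) | !is.finite(log_df$light_lumft2)))
    stop_validation("non-finite logger readings")

  spot_df <- NULL
  if (!is.null(spot)) {
    spot_df <- check_cols(read_table_arg(spot, "env_spot"), SPOT_COLS,
                          "env_spot")
    spot_df$week <- as.integer(spot_df$week)
    spot_df$trap_location <- as.integer(spot_df$trap_location)
    if (nrow(spot_df)) {
      if (any(!spot_df$phase %in% c("start", "end")))
        stop_validation("spot phase must be 'start' or 'end'")
      neg <- c(spot_df$turbidity_ntu, spot_df$do_mgl)
      if (any(neg[is.finite(neg)] < 0))
        stop_validation("turbidity and dissolved oxygen must be >= 0")
    }
  }

  skey <- unique(log_df[, c("site_id", "week")])
  out <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(skey))) {
    sl <- log_df[log_df$site_id == skey$site_id[i] &
                   log_df$week == skey$week[i], , drop = FALSE]
    if (!is.null(window)) {
      w <- window[window$site_id == skey$site_id[i] &
                    window$week == skey$week[i], , drop = FALSE]
      win <- c(parse_iso_time(w$window_start[1]),
               parse_iso_time(w$window_end[1]))
    } else {
      win <- range(sl$timestamp)
    }
    for (tr in sort(unique(sl$trap_location))) {
      tl <- sl[sl$trap_location == tr, , drop = FALSE]
      tl <- tl[order(tl$timestamp), , drop = FALSE]
      inside <- tl$timestamp >= win[1] & tl$timestamp <= win[2]
      if (!any(inside)) {
        dropped <- c(dropped, sprintf("(%s, week %d, trap %d)",
                                      skey$site_id[i], skey$week[i], tr))
        next
      }
      flags <- character(0)
      if (!all(inside)) {
        tl <- tl[inside, , drop = FALSE]
        flags <- c(flags, "readings_outside_window_trimmed")
      }
      turb <- c(start = NA_real_, end = NA_real_)
      dox <- c(start = NA_real_, end = NA_real_)
      if (!is.null(spot_df)) {
        sp <- spot_df[spot_df$site_id == skey$site_id[i] &
                        spot_df$week == skey$week[i] &
                        spot_df$trap_location == tr, , drop = FALSE]
        for (ph in c("start", "end")) {
          r <- sp[sp$phase == ph, , drop = FALSE]
          if (nrow(r)) {
            turb[ph] <- r$turbidity_ntu[1]
            dox[ph] <- r$do_mgl[1]
          }
        }
        if (anyNA(turb) || anyNA(dox)) flags <- c(flags, "missing_spot_phase")
      }
      out[[length(out) + 1L]] <- list(
        site_id = skey$site_id[i], week = skey$week[i], trap_location = tr,
        series = tl[, c("timestamp", "temperature_c", "light_lumft2")],
        turbidity = turb, do = dox, flags = flags)
    }
  }
  if (length(dropped))
    warning("logger series entirely outside the session window, excluded: ",
            paste(dropped, collapse = "; "), call. = FALSE)
  structure(out, class = "env_series")
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("<env_series> %d trap-session records\n", length(x)))
  invisible(x)
}
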