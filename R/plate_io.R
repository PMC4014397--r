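#' Construct a per-well plate-reader time series
#'
#' A `plate_series` holds the raw optical-density (600 nm) and fluorescence
#' (535 nm) traces for one well, together with its plate-map metadata: the
#' promoter carried by the reporter strain, the condition set (supplements
#' added to the base medium), and the replicate day.
#'
#' @param well_id well identifier (string).
#' @param promoter promoter name; background-control wells carry the
#'   promoterless vector and are flagged via `is_background_control`.
#' @param condition_set character vector of supplement labels (canonicalized).
#' @param replicate_day integer replicate/day label.
#' @param time_min numeric vector of measurement times in minutes; strictly
#'   increasing.
#' @param od optical density values, same length as `time_min`, non-negative.
#' @param fluo fluorescence values, same length as `time_min`.
#' @param is_background_control logical flag for promoterless control wells.
#' @return object of class `plate_series`.
#' @export
plate_series <- function(well_id, promoter, condition_set, replicate_day,
                         time_min, od, fluo, is_background_control = FALSE) {
  time_min <- as.numeric(time_min)
  od <- as.numeric(od)
  fluo <- as.numeric(fluo)
  if (length(time_min) < 1L)
    stop("plate_series: empty time vector for well '", well_id, "'")
  if (any(diff(time_min) <= 0))
    stop("plate_series: time_min not strictly increasing in well '", well_id, "'")
  if (length(od) != length(time_min) || length(fluo) != length(time_min))
    stop("plate_series: od/fluo length mismatch in well '", well_id, "'")
  if (any(od < 0))
    stop("plate_series: negative OD in well '", well_id, "'")
  structure(
    list(well_id = as.character(well_id),
         promoter = as.character(promoter),
         condition_set = condition_set(condition_set),
         replicate_day = as.integer(replicate_day),
         time_min = time_min, od = od, fluo = fluo,
         is_background_control = isTRUE(is_background_control)),
    class = "plate_series")
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf("<plate_series> well %s  promoter %s  condition %s  day %d  (%d points, %.0f-%.0f min)%s\n",
              x$well_id, x$promoter,
              if (length(x$condition_set)) condition_key(x$condition_set) else "(base)",
              x$replicate_day, length(x$time_min),
              min(x$time_min), max(x$time_min),
              if (x$is_background_control) "  [background control]" else ""))
  invisible(x)
}

as_plate_collection <- function(x) {
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "plate_series")))
  names(x) <- vapply(x, `[[`, character(1), "well_id")
  structure(x, class = "plate_collection")
}

#' @export
print.plate_collection <- function(x, ...) {
  conds <- unique(vapply(x, function(s) condition_key(s$condition_set), character(1)))
  proms <- unique(vapply(x, `[[`, character(1), "promoter"))
  cat(sprintf("<plate_collection> %d wells, %d promoters, %d condition sets, days %s\n",
              length(x), length(proms), length(conds),
              paste(sort(unique(vapply(x, `[[`, integer(1), "replicate_day"))),
                    collapse = ",")))
  invisible(x)
}

#' Read a plate-reader table and plate map
#'
#' The plate table is a wide CSV with one `time_min` column and two columns
#' per well, named `<well>.od` and `<well>.fluo` (the dialect written by
#' [write_plate_table()] and typical of plate-reader exports). The plate map
#' is a CSV with columns `well, promoter, conditions, day, is_control`, where
#' `conditions` joins supplement labels with `"+"` (empty = base medium).
#' Both readers accept gzip-compressed files.
#'
#' @param path path to the plate table CSV (optionally .gz).
#' @param plate_map path to the plate map CSV (optionally .gz).
#' @return a `plate_collection`: list of [plate_series()], one per well.
#' @export
read_plate_table <- function(path, plate_map) {
  tab <- utils::read.csv(path, check.names = FALSE)
  map <- utils::read.csv(plate_map, colClasses = c(conditions = "character"))
  need <- c("well", "promoter", "conditions", "day", "is_control")
  if (!all(need %in% names(map)))
    stop("plate map missing columns: ", paste(setdiff(need, names(map)), collapse = ", "))
  if (!"time_min" %in% names(tab))
    stop("plate table has no 'time_min' column")
  time_min <- tab$time_min
  if (any(diff(time_min) <= 0))
    stop("plate table time_min not strictly increasing")
  wells_in_table <- unique(sub("\\.(od|fluo)$", "", setdiff(names(tab), "time_min")))
  missing_wells <- setdiff(map$well, wells_in_table)
  if (length(missing_wells))
    stop("plate map well(s) absent from table: ", paste(missing_wells, collapse = ", "))
  unmapped <- setdiff(wells_in_table, map$well)
  if (length(unmapped))
    stop("table well(s) absent from plate map: ", paste(unmapped, collapse = ", "))
  out <- lapply(seq_len(nrow(map)), function(i) {
    w <- map$well[i]
    oc <- paste0(w, ".od"); fc <- paste0(w, ".fluo")
    if (!oc %in% names(tab) || !fc %in% names(tab))
      stop("well '", w, "' lacks .od/.fluo columns in table")
    plate_series(well_id = w, promoter = map$promoter[i],
                 condition_set = condition_set(map$conditions[i]),
                 replicate_day = map$day[i],
                 time_min = time_min, od = tab[[oc]], fluo = tab[[fc]],
                 is_background_control = as.logical(map$is_control[i]))
  })
  as_plate_collection(out)
}

#' Write a plate collection in the wide-CSV dialect
#'
#' Inverse of [read_plate_table()]. All series must share one time grid.
#'
#' @param collection a `plate_collection` or list of [plate_series()].
#' @param path output path for the plate table CSV.
#' @param map_path output path for the plate map CSV.
#' @return invisibly, the two paths.
#' @export
write_plate_table <- function(collection, path, map_path) {
  stopifnot(length(collection) >= 1L)
  t0 <- collection[[1]]$time_min
  for (s in collection)
    if (!isTRUE(all.equal(s$time_min, t0)))
      stop("write_plate_table: wells are not on a common time grid")
  tab <- data.frame(time_min = t0, check.names = FALSE)
  for (s in collection) {
    tab[[paste0(s$well_id, ".od")]] <- s$od
    tab[[paste0(s$well_id, ".fluo")]] <- s$fluo
  }
  map <- data.frame(
    well = vapply(collection, `[[`, character(1), "well_id"),
    promoter = vapply(collection, `[[`, character(1), "promoter"),
    conditions = vapply(collection, function(s) condition_key(s$condition_set), character(1)),
    day = vapply(collection, `[[`, integer(1), "replicate_day"),
    is_control = vapply(collection, `[[`, logical(1), "is_background_control"))
  utils::write.csv(tab, path, row.names = FALSE)
  utils::write.csv(map, map_path, row.names = FALSE)
  invisible(c(path, map_path))
}

#' Subtract background fluorescence using a promoterless-control well
#'
#' Fluorescence from a reporter strain carrying the promoterless vector is
#' subtracted point-wise from the well's GFP trace. If the control was
#' measured on a different time grid it is linearly interpolated onto the
#' series' grid first. OD is left untouched. By default negative values after
#' subtraction are retained so the downstream derivative sees unbiased noise;
#' set `clip = TRUE` to floor at zero.
#'
#' @param series a [plate_series()].
#' @param control a [plate_series()] flagged as background control.
#' @param clip floor the subtracted fluorescence at 0? Default `FALSE`.
#' @return the series with `fluo` replaced by `fluo - control$fluo`.
#' @export
subtract_background <- function(series, control, clip = FALSE) {
  if (!isTRUE(control$is_background_control))
    stop("subtract_background: control well '", control$well_id,
         "' is not flagged as background control")
  rng_s <- range(series$time_min); rng_c <- range(control$time_min)
  ov <- min(rng_s[2], rng_c[2]) - max(rng_s[1], rng_c[1])
  if (ov < 0.5 * diff(rng_s))
    stop("subtract_background: control time range overlaps series by < 50%")
  if (identical(control$time_min, series$time_min)) {
    bg <- control$fluo
  } else {
    bg <- stats::approx(control$time_min, control$fluo, xout = series$time_min,
                        rule = 2)$y
  }
  series$fluo <- series$fluo - bg
  if (clip) series$fluo <- pmax(series$fluo, 0)
  series
}

#' Background-subtract every well of a collection
#'
#' Each non-control well is matched to the promoterless-control well with the
#' same condition set and replicate day.
#'
#' @param collection a `plate_collection`.
#' @param clip passed to [subtract_background()].
#' @return the collection with backgrounds subtracted; control wells dropped.
#' @export
subtract_background_all <- function(collection, clip = FALSE) {
  key <- function(s) paste(condition_key(s$condition_set), s$replicate_day, sep = "|")
  is_ctrl <- vapply(collection, `[[`, logical(1), "is_background_control")
  ctrls <- collection[is_ctrl]
  ctrl_keys <- vapply(ctrls, key, character(1))
  out <- lapply(collection[!is_ctrl], function(s) {
    i <- match(key(s), ctrl_keys)
    if (is.na(i))
      stop("no background control for condition '", condition_key(s$condition_set),
           "' day ", s$replicate_day)
    subtract_background(s, ctrls[[i]], clip = clip)
  })
  as_plate_collection(out)
}
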