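#' Configuration for the synthetic plate-experiment generator
#'
#' Defaults emulate the batch-culture reporter assay the analysis is built
#' for: 8-minute sampling from inoculation to stationary phase (8-22 h
#' depending on the condition's growth rate), about 6 generations of growth
#' from a 1:500-style dilution to a final OD near 0.15, four replicate days
#' with ~14% day-to-day multiplicative error, four supplement labels giving
#' 15 condition combinations, and promoters whose cross-condition dynamics
#' lies in a 1-2 dimensional shape space, with a configurable count of
#' sequential-regulation (diauxie-like) violators.
#'
#' @param labels single-supplement labels (default `c("A","B","C","D")`).
#' @param n_days replicate days (default 4).
#' @param day_sigma day-to-day log-normal sigma (default 0.14).
#' @param od_sigma per-time-point OD measurement noise (OD units).
#' @param fluo_sigma per-time-point fluorescence measurement noise.
#' @param background_fluo constant background fluorescence level.
#' @param dt_min sampling interval in minutes (default 8).
#' @param od0 inoculation OD (default `0.15 / 2^6`: six doublings below the
#'   carrying capacity).
#' @param od_max carrying-capacity OD (default 0.15).
#' @param rates named single-condition logistic growth rates (1/min); the
#'   defaults span saturation times of roughly 12-22 h within the assay's
#'   8-22 h envelope, with the amino-acid-supplemented condition fastest.
#' @param combo_rate_penalty multiplicative slowdown per extra supplement in
#'   a combination (combined rate = geometric mean of member rates times
#'   this penalty per additional supplement).
#' @param max_hours hard cap on run duration (default 22).
#' @param frac_single_shape fraction of promoters whose dynamics varies only
#'   in amplitude across conditions (one latent shape; default 1/3).
#' @param n_violators number of sequential-regulation violator promoters
#'   (default 1).
#' @param violator_combo condition set in which violators switch (default
#'   the first two labels).
#' @param amp1_range,amp2_range ranges for the random positive loadings of
#'   the two latent shapes (activity units).
#' @param amp2_minor_range residual second-shape loading range for
#'   amplitude-dominated ("one-shape") promoters. Real promoters are never
#'   exactly rank one (the best single-component promoters leave a couple of
#'   percent of variance unexplained), and an exactly rank-one basis makes
#'   mixture weights unidentifiable; a small residual loading keeps such
#'   promoters realistic.
#' @param bump_center_range,bump_width center range and width (generations)
#'   of the second latent shape's Gaussian bump.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(labels = c("A", "B", "C", "D"),
                             n_days = 4L,
                             day_sigma = 0.14,
                             od_sigma = 3e-4,
                             fluo_sigma = 5,
                             background_fluo = 100,
                             dt_min = 8,
                             od0 = 0.15 / 2^6,
                             od_max = 0.15,
                             rates = c(A = 0.0115, B = 0.0052,
                                       C = 0.0088, D = 0.0070),
                             combo_rate_penalty = 0.95,
                             max_hours = 22,
                             frac_single_shape = 1 / 3,
                             n_violators = 1L,
                             violator_combo = NULL,
                             amp1_range = c(50, 200),
                             amp2_range = c(20, 100),
                             amp2_minor_range = c(5, 25),
                             bump_center_range = c(1.5, 4.5),
                             bump_width = 0.8) {
  cfg <- list(labels = condition_set(labels), n_days = as.integer(n_days),
              day_sigma = day_sigma, od_sigma = od_sigma,
              fluo_sigma = fluo_sigma, background_fluo = background_fluo,
              dt_min = dt_min, od0 = od0, od_max = od_max, rates = rates,
              combo_rate_penalty = combo_rate_penalty, max_hours = max_hours,
              frac_single_shape = frac_single_shape,
              n_violators = as.integer(n_violators),
              violator_combo = condition_set(violator_combo %||% labels[1:2]),
              amp1_range = amp1_range, amp2_range = amp2_range,
              amp2_minor_range = amp2_minor_range,
              bump_center_range = bump_center_range, bump_width = bump_width)
  if (length(cfg$labels) < 2) stop("synthetic_config: need >= 2 labels")
  if (cfg$day_sigma < 0) stop("synthetic_config: invalid field day_sigma")
  if (cfg$od_max <= cfg$od0) stop("synthetic_config: od_max must exceed od0")
  if (any(cfg$rates <= 0)) stop("synthetic_config: invalid field rates")
  if (!all(cfg$labels %in% names(cfg$rates)))
    stop("synthetic_config: invalid field rates (missing label rates)")
  if (!all(cfg$violator_combo %in% cfg$labels))
    stop("synthetic_config: invalid field violator_combo")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate the latent ground truth behind a synthetic plate experiment
#'
#' Each promoter receives one or two latent activity shapes on the
#' generation axis: shape 1 follows the instantaneous growth rate
#' (`1 - 2^(g - G)`, with `G` the total number of doublings to carrying
#' capacity), so the first principal component is growth-coupled by
#' construction; shape 2 is a Gaussian bump with a random center. About a
#' third of the promoters (configurable) are amplitude-dominated: their
#' second-shape loading is a small residual, so a single component explains
#' nearly -- not exactly -- all of their cross-condition variance, as in
#' real reporter data. Each
#' single condition gets random positive loadings on the shapes; each
#' combined condition's true curve is the exact simplex mixture of the
#' single-condition curves, with weights obtained by restricting and
#' renormalizing one flat-simplex point per promoter -- so the weight
#' hierarchy is self-consistent and the pair-to-cocktail prediction
#' formula's premise holds by construction. A configured number of
#' violator promoters instead get switch-like (sequential-regulation)
#' dynamics in one designated combination.
#'
#' @param n_promoters number of promoters (>= 1).
#' @param config a [synthetic_config()].
#' @param seed RNG seed; the same seed reproduces the identical truth.
#' @return object of class `synthetic_truth`.
#' @export
generate_truth <- function(n_promoters, config = synthetic_config(), seed = 1L) {
  stopifnot(n_promoters >= 1L)
  if (config$n_violators > n_promoters)
    stop("generate_truth: invalid config field n_violators (exceeds n_promoters)")
  labels <- config$labels
  g_total <- log2(config$od_max / config$od0)
  with_seed(seed, {
    proms <- lapply(seq_len(n_promoters), function(i) {
      wstar <- stats::rexp(length(labels))
      wstar <- wstar / sum(wstar)
      names(wstar) <- labels
      two_shape <- stats::runif(1) > config$frac_single_shape
      amp1 <- stats::runif(length(labels), config$amp1_range[1], config$amp1_range[2])
      amp2 <- if (two_shape)
        stats::runif(length(labels), config$amp2_range[1], config$amp2_range[2])
      else
        stats::runif(length(labels), config$amp2_minor_range[1],
                     config$amp2_minor_range[2])
      names(amp1) <- names(amp2) <- labels
      list(name = sprintf("P%03d", i),
           n_shapes = if (two_shape) 2L else 1L,
           wstar = wstar, amp1 = amp1, amp2 = amp2,
           bump_center = stats::runif(1, config$bump_center_range[1],
                                      config$bump_center_range[2]),
           is_violator = FALSE,
           switch_gen = stats::runif(1, 2.5, 3.5),
           pre_level = 10, post_level = 200)
    })
    if (config$n_violators > 0) {
      idx <- sample.int(n_promoters, config$n_violators)
      for (i in idx) proms[[i]]$is_violator <- TRUE
    }
    names(proms) <- vapply(proms, `[[`, character(1), "name")
    structure(list(promoters = proms, config = config, g_total = g_total,
                   seed = seed), class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  nv <- sum(vapply(x$promoters, `[[`, logical(1), "is_violator"))
  n1 <- sum(vapply(x$promoters, `[[`, integer(1), "n_shapes") == 1L)
  cat(sprintf("<synthetic_truth> %d promoters (%d one-shape, %d violators), labels %s, seed %d\n",
              length(x$promoters), n1, nv,
              paste(x$config$labels, collapse = ","), x$seed))
  invisible(x)
}

#' True simplex weights for any condition subset
#'
#' Restriction of the promoter's full simplex point to the subset,
#' renormalized to sum to one.
#'
#' @param truth a [generate_truth()] object.
#' @param promoter promoter name.
#' @param conditions condition subset (labels or key).
#' @return named weights over the subset's single conditions.
#' @export
true_weights <- function(truth, promoter, conditions) {
  w <- truth$promoters[[promoter]]$wstar
  S <- condition_set(conditions)
  w[S] / sum(w[S])
}

#' True activity as a function of generations
#'
#' Returns the promoter's latent activity curve in the given condition set
#' as a vectorized function of the generation axis.
#'
#' @inheritParams true_weights
#' @return function mapping generations to activity.
#' @export
true_activity_fun <- function(truth, promoter, conditions) {
  p <- truth$promoters[[promoter]]
  cfg <- truth$config
  S <- condition_set(conditions)
  G <- truth$g_total
  shape1 <- function(g) pmax(1 - 2^(g - G), 0)
  shape2 <- function(g) exp(-(g - p$bump_center)^2 / (2 * cfg$bump_width^2))
  if (p$is_violator && identical(S, cfg$violator_combo)) {
    return(function(g) p$pre_level + (p$post_level - p$pre_level) /
             (1 + exp(-(g - p$switch_gen) / 0.15)))
  }
  w <- true_weights(truth, promoter, S)
  function(g) {
    a <- 0
    for (i in S)
      a <- a + w[[i]] * (p$amp1[[i]] * shape1(g) + p$amp2[[i]] * shape2(g))
    a
  }
}

# Logistic OD trajectory and the condition's growth rate / duration.
combo_rate <- function(cfg, S) {
  r <- exp(mean(log(cfg$rates[S]))) * cfg$combo_rate_penalty^(length(S) - 1)
  unname(r)
}

condition_time_grid <- function(cfg, S) {
  r <- combo_rate(cfg, S)
  t_end <- log(99 * (cfg$od_max / cfg$od0 - 1)) / r
  t_end <- min(t_end, cfg$max_hours * 60)
  seq(0, ceiling(t_end / cfg$dt_min) * cfg$dt_min, by = cfg$dt_min)
}

logistic_od <- function(cfg, S, t) {
  r <- combo_rate(cfg, S)
  K <- cfg$od_max; x0 <- cfg$od0
  K * x0 * exp(r * t) / (K + x0 * (exp(r * t) - 1))
}

cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (y[-1] + y[-length(y)]) / 2))
}

#' Render a synthetic truth into plate-reader wells
#'
#' For every condition set and replicate day, OD follows logistic growth at
#' the condition's rate on an `dt_min`-minute grid until just short of
#' carrying capacity (capped at `max_hours`); each promoter's GFP trace
#' integrates `dG/dt = activity(generations(t)) * OD(t)` by the trapezoid
#' rule, scaled by a log-normal day factor (sigma = `day_sigma` per
#' promoter, condition and day), plus constant background fluorescence and
#' Gaussian per-time-point measurement noise. A promoterless background
#' control well is emitted per (condition, day) group. Wells are arranged on
#' 96-well plates (rows A-H, columns 1-12), one or more plates per group;
#' measured values are quantized to instrument-like precision so written CSV
#' tables round-trip exactly.
#'
#' @param truth a [generate_truth()] object.
#' @param seed RNG seed for the rendering noise.
#' @param condition_sets which condition sets to render (default: all
#'   non-empty combinations of the config labels).
#' @param days which replicate days (default `1:n_days`).
#' @param noise set `FALSE` for a noiseless render (no day factors, no
#'   measurement noise, no background).
#' @return a `plate_collection`; attribute `"layout"` maps wells to plates.
#' @export
render_plate <- function(truth, seed = 1L,
                         condition_sets = NULL, days = NULL, noise = TRUE) {
  cfg <- truth$config
  if (is.null(condition_sets))
    condition_sets <- condition_combinations(cfg$labels)
  if (is.null(days)) days <- seq_len(cfg$n_days)
  proms <- truth$promoters
  wells <- list(); layout <- list()
  plate_no <- 0L
  pos_names <- as.vector(outer(LETTERS[1:8], 1:12, paste0))
  with_seed(seed, {
    for (S in condition_sets) {
      t <- condition_time_grid(cfg, S)
      od <- logistic_od(cfg, S, t)
      g <- log2(od / cfg$od0)
      for (d in days) {
        chunk_starts <- seq(1, length(proms), by = 95)
        for (cs in chunk_starts) {
          plate_no <- plate_no + 1L
          plate_id <- sprintf("p%03d", plate_no)
          chunk <- proms[cs:min(cs + 94, length(proms))]
          pos <- 1L
          for (p in chunk) {
            afun <- true_activity_fun(truth, p$name, S)
            day_fac <- if (noise) exp(stats::rnorm(1, 0, cfg$day_sigma)) else 1
            act <- day_fac * afun(g)
            gfp <- cumtrapz(t, act * od)
            fluo <- gfp
            od_m <- od
            if (noise) {
              fluo <- fluo + cfg$background_fluo +
                stats::rnorm(length(t), 0, cfg$fluo_sigma)
              od_m <- pmax(od + stats::rnorm(length(t), 0, cfg$od_sigma), 1e-6)
            }
            wid <- paste0(plate_id, ".", pos_names[pos])
            wells[[wid]] <- plate_series(
              wid, p$name, S, d, round(t, 2),
              round(od_m, 6), round(fluo, 3))
            layout[[wid]] <- data.frame(well = wid, plate = plate_id,
                                        position = pos_names[pos])
            pos <- pos + 1L
          }
          # promoterless control for this plate
          bg <- if (noise)
            cfg$background_fluo + stats::rnorm(length(t), 0, cfg$fluo_sigma)
          else rep(0, length(t))
          od_m <- if (noise)
            pmax(od + stats::rnorm(length(t), 0, cfg$od_sigma), 1e-6)
          else od
          wid <- paste0(plate_id, ".", pos_names[pos])
          wells[[wid]] <- plate_series(
            wid, "promoterless", S, d, round(t, 2),
            round(od_m, 6), round(bg, 3), is_background_control = TRUE)
          layout[[wid]] <- data.frame(well = wid, plate = plate_id,
                                      position = pos_names[pos])
        }
      }
    }
  })
  out <- as_plate_collection(wells)
  attr(out, "layout") <- do.call(rbind, unname(layout))
  out
}

#' Write a rendered collection as per-plate CSV tables
#'
#' Emits one plate-table/plate-map CSV pair per physical plate (wells of a
#' plate share a time grid) in the dialect read by [read_plate_table()].
#'
#' @param collection a `plate_collection` from [render_plate()].
#' @param dir output directory (created if needed).
#' @return invisibly, data frame of (plate, table, map) paths.
#' @export
write_synthetic_plates <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- attr(collection, "layout")
  if (is.null(layout)) stop("collection has no plate layout attribute")
  plates <- split(layout$well, layout$plate)
  paths <- lapply(names(plates), function(p) {
    tab <- file.path(dir, paste0(p, "_table.csv"))
    map <- file.path(dir, paste0(p, "_map.csv"))
    write_plate_table(as_plate_collection(collection[plates[[p]]]), tab, map)
    data.frame(plate = p, table = tab, map = map)
  })
  invisible(do.call(rbind, paths))
}

#' Write the ground truth as CSV
#'
#' One row per promoter: full-simplex weights, shape count, violator flag
#' and switch parameters -- the reference for end-to-end recovery tests.
#'
#' @param truth a [generate_truth()] object.
#' @param path output CSV path.
#' @return invisibly, the data frame written.
#' @export
write_truth_csv <- function(truth, path) {
  labs <- truth$config$labels
  d <- do.call(rbind, lapply(truth$promoters, function(p) {
    r <- data.frame(promoter = p$name, n_shapes = p$n_shapes,
                    is_violator = p$is_violator)
    for (l in labs) r[[paste0("wstar_", l)]] <- unname(p$wstar[l])
    r$bump_center <- p$bump_center
    r$switch_gen <- p$switch_gen
    r
  }))
  rownames(d) <- NULL
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
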