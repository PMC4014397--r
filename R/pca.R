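#' Assemble a promoter's condition-by-grid activity matrix
#'
#' Stacks one promoter's activity curves into a matrix with one row per
#' condition set (replicate days averaged point-wise by the arithmetic mean)
#' and one column per shared-grid generation. Rows are ordered canonically:
#' by condition-set size, then lexicographically by key.
#'
#' @param curves list of [activity_curve()] for a single promoter, all on
#'   the identical generation grid (see [resample_to_common_grid()]).
#' @return numeric matrix (conditions x grid points) with row names the
#'   condition keys and attribute `"generations"` carrying the grid.
#' @export
condition_matrix <- function(curves) {
  stopifnot(length(curves) >= 1L)
  prom <- unique(vapply(curves, `[[`, character(1), "promoter"))
  if (length(prom) != 1L)
    stop("condition_matrix: curves span multiple promoters: ",
         paste(prom, collapse = ", "))
  grid <- curves[[1]]$generations
  for (cur in curves)
    if (!isTRUE(all.equal(cur$generations, grid)))
      stop("condition_matrix: curves are not on the identical shared grid")
  keys <- vapply(curves, function(cur) condition_key(cur$condition_set), character(1))
  days <- vapply(curves, `[[`, integer(1), "replicate_day")
  if (anyDuplicated(paste(keys, days)))
    stop("condition_matrix: duplicate (promoter, condition, day) curves")
  ukeys <- unique(keys)
  sizes <- lengths(strsplit(ukeys, "+", fixed = TRUE))
  ukeys <- ukeys[order(sizes, ukeys)]
  m <- t(vapply(ukeys, function(k) {
    rows <- vapply(curves[keys == k], `[[`, numeric(length(grid)), "activity")
    rowMeans(as.matrix(rows))
  }, numeric(length(grid))))
  rownames(m) <- ukeys
  attr(m, "generations") <- grid
  attr(m, "promoter") <- prom
  m
}

#' Principal component curves of a promoter's dynamics across conditions
#'
#' Singular value decomposition of the (by default un-centered) condition x
#' grid matrix. The top-k right singular vectors are the promoter's
#' principal dynamic curves; the variance fraction of component i is
#' \eqn{\sigma_i^2 / \sum_j \sigma_j^2}; the loadings reconstruct each
#' condition's curve as loadings %*% components. Un-centered decomposition is
#' the default because each condition's curve is modeled as a plain linear
#' combination of the component curves, with no mean offset -- a promoter
#' whose dynamics only changes amplitude across conditions is then exactly
#' rank 1.
#'
#' @param m condition x grid matrix from [condition_matrix()].
#' @param k number of components to retain (default `min(dim(m))`).
#' @param center subtract the column mean first? Default `FALSE`.
#' @return object of class `principal_shapes` with fields `promoter`,
#'   `components` (k x grid), `variance_fractions`, `condition_loadings`
#'   (conditions x k), `conditions`, `generations`, `centered`.
#' @export
principal_shapes <- function(m, k = min(dim(m)), center = FALSE) {
  m <- as.matrix(m)
  if (k > min(dim(m))) stop("k exceeds min(rows, cols)")
  if (all(m == 0)) stop("principal_shapes: all-zero matrix")
  grid <- attr(m, "generations")
  mm <- if (center) sweep(m, 2, colMeans(m)) else m
  sv <- svd(mm)
  vf <- sv$d^2 / sum(sv$d^2)
  structure(list(
    promoter = attr(m, "promoter") %||% "",
    components = t(sv$v[, seq_len(k), drop = FALSE]),
    variance_fractions = vf[seq_len(k)],
    condition_loadings = sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sv$d[seq_len(k)], nrow = k),
    conditions = rownames(m),
    generations = grid,
    centered = center), class = "principal_shapes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.principal_shapes <- function(x, ...) {
  cat(sprintf("<principal_shapes> %s | %d components over %d conditions | var fractions: %s\n",
              x$promoter, nrow(x$components), length(x$conditions),
              paste(sprintf("%.3f", x$variance_fractions), collapse = ", ")))
  invisible(x)
}

#' Fraction of variance explained by the first k components
#'
#' @param shapes a [principal_shapes()] object.
#' @param k number of leading components.
#' @return sum of the first `k` variance fractions, in `[0, 1]`.
#' @export
explained_by_first_k <- function(shapes, k) {
  if (k > length(shapes$variance_fractions))
    stop("k exceeds the number of available components")
  sum(shapes$variance_fractions[seq_len(k)])
}

#' Randomized null distribution of the 2-PC variance fraction
#'
#' For each shuffle, entries are permuted independently within each grid
#' column across conditions (preserving every grid point's marginal across
#' conditions), and the fraction of variance explained by the first two
#' components of the shuffled matrix is recomputed. The observed 2-PC
#' fraction of structured dynamics should exceed the upper tail of this
#' null.
#'
#' @param m condition x grid matrix.
#' @param n_shuffles number of shuffles (>= 1).
#' @param seed RNG seed for reproducibility.
#' @param center passed to [principal_shapes()].
#' @return numeric vector of `n_shuffles` null 2-PC variance fractions.
#' @export
randomized_null <- function(m, n_shuffles, seed = 1L, center = FALSE) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  m <- as.matrix(m)
  kk <- min(2L, min(dim(m)))
  with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    ms <- apply(m, 2, function(col) col[sample.int(length(col))])
    if (is.null(dim(ms))) ms <- matrix(ms, nrow = nrow(m))
    explained_by_first_k(principal_shapes(ms, k = kk, center = center), kk)
  }, numeric(1)))
}

#' Squared correlation between the first principal curve and growth rate
#'
#' The first principal component of most promoters tracks the instantaneous
#' growth rate; this accessor quantifies that as the squared Pearson
#' correlation between the PC1 curve and a growth-rate curve on the same
#' generation grid.
#'
#' @param shapes a [principal_shapes()] object.
#' @param growth a `growth_rate_curve` (or numeric vector) on the same grid.
#' @return R-squared in `[0, 1]`, or `NA` if either input has zero variance.
#' @export
pc1_growth_correlation <- function(shapes, growth) {
  g <- if (is.numeric(growth)) growth else growth$rate
  pc1 <- shapes$components[1, ]
  if (length(g) != length(pc1))
    stop("growth curve and PC1 are not on the same grid")
  if (stats::sd(pc1) == 0 || stats::sd(g) == 0) return(NA_real_)
  stats::cor(pc1, g)^2
}

#' Write principal shapes and a per-promoter summary as CSV
#'
#' @param shapes_list named list of [principal_shapes()] (one per promoter).
#' @param shapes_path CSV of (promoter, component, generation, value).
#' @param summary_path CSV of (promoter, var_frac_1, var_frac_2,
#'   pc1_growth_R2); R2 column filled when `growth_r2` is supplied.
#' @param growth_r2 optional named numeric vector of per-promoter R2 values.
#' @return invisibly, the summary data frame.
#' @export
write_shapes_csv <- function(shapes_list, shapes_path, summary_path,
                             growth_r2 = NULL) {
  long <- do.call(rbind, lapply(shapes_list, function(sh) {
    k <- nrow(sh$components)
    data.frame(promoter = sh$promoter,
               component = rep(seq_len(k), each = ncol(sh$components)),
               generation = rep(sh$generations %||% seq_len(ncol(sh$components)), k),
               value = as.vector(t(sh$components)))
  }))
  utils::write.csv(long, shapes_path, row.names = FALSE)
  summ <- data.frame(
    promoter = vapply(shapes_list, `[[`, character(1), "promoter"),
    var_frac_1 = vapply(shapes_list, function(s) s$variance_fractions[1], numeric(1)),
    var_frac_2 = vapply(shapes_list, function(s)
      if (length(s$variance_fractions) >= 2) s$variance_fractions[2] else NA_real_,
      numeric(1)))
  summ$pc1_growth_R2 <- if (!is.null(growth_r2)) growth_r2[summ$promoter] else NA_real_
  utils::write.csv(summ, summary_path, row.names = FALSE)
  invisible(summ)
}
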