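#' Oxygen-zone classification of a depth/O2 pair
#'
#' Five water-column zones are defined by joint depth and dissolved-O2
#' boxes: upper oxic (15-30 m, O2 > 200 uM), upper oxycline (50-85 m,
#' 10-200 uM), upper OMZ (70-125 m, < 10 uM), core OMZ (200-300 m,
#' < 5 uM) and lower oxycline (500-1000 m, 5-50 uM). Depth windows are
#' inclusive on both ends; O2 intervals are closed below and open above
#' (so 10 uM at 80 m is upper oxycline, not upper OMZ). Inputs matching
#' no box, or missing inputs, return "unclassified".
#'
#' @param depth Depth in m (vectorised).
#' @param o2 Dissolved O2 in uM (vectorised).
#' @return Character vector of zone labels.
#' @export
classify_zone <- function(depth, o2) {
  n <- max(length(depth), length(o2))
  depth <- rep_len(depth, n); o2 <- rep_len(o2, n)
  out <- rep("unclassified", n)
  miss <- is.na(depth) | is.na(o2)
  if (any(miss)) warning(sum(miss), " sample(s) with missing depth or O2")
  inbox <- function(dlo, dhi, olo, ohi) {
    !miss & depth >= dlo & depth <= dhi & o2 >= olo & o2 < ohi
  }
  out[inbox(15, 30, 200, Inf) & o2 > 200] <- "upper_oxic"
  out[inbox(50, 85, 10, 200)] <- "upper_oxycline"
  out[inbox(70, 125, 0, 10)] <- "upper_omz"
  out[inbox(200, 300, 0, 5)] <- "core_omz"
  out[inbox(500, 1000, 5, 50)] <- "lower_oxycline"
  out
}

#' Assemble a geochemistry sample table
#'
#' Validates columns, derives the Fe:Cu molar ratio (dFe/dCu, both nM)
#' and the oxygen-zone label.
#'
#' @param df Data frame with columns sample_id, depth, temperature, o2,
#'   no3, no2, po4, dfe, dcu (missing values allowed).
#' @return A `GeoSamples` data frame with added `fe_cu_ratio` and `zone`.
#' @export
geo_samples <- function(df) {
  need <- c("sample_id", "depth", "o2", "dfe", "dcu")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing geochemistry column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("temperature", "no3", "no2", "po4"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (any(df$depth < 0, na.rm = TRUE)) stop("negative depth")
  df$fe_cu_ratio <- ifelse(!is.na(df$dfe) & !is.na(df$dcu) & df$dcu > 0,
                           df$dfe / df$dcu, NA_real_)
  df$zone <- classify_zone(df$depth, df$o2)
  class(df) <- c("GeoSamples", "data.frame")
  df
}

#' Construct a linear Fe:Cu vs O2 fit from known coefficients
#'
#' Useful for evaluating a published fit (e.g. a basin-scale transect
#' regression) without the underlying points.
#'
#' @param slope Ratio change per uM O2.
#' @param intercept Ratio at 0 uM O2.
#' @param r_squared Coefficient of determination (NA if unknown).
#' @param n Number of points behind the fit.
#' @return A `LinearFit` object.
#' @export
linear_fit <- function(slope, intercept, r_squared = NA_real_, n = 2L) {
  stopifnot(n >= 2, is.na(r_squared) || (r_squared >= 0 && r_squared <= 1))
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n = as.integer(n)),
            class = "LinearFit")
}

#' @export
print.LinearFit <- function(x, ...) {
  cat(sprintf("Fe:Cu = %.4g [O2 uM] + %.4g  (R^2 = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Ordinary least-squares fit of Fe:Cu ratio on dissolved O2
#'
#' @param samples A `GeoSamples` frame (or any frame with `fe_cu_ratio`
#'   and `o2`).
#' @return A `LinearFit` with slope, intercept, r_squared and n.
#' @export
fit_fe_cu_vs_o2 <- function(samples) {
  ok <- !is.na(samples$fe_cu_ratio) & !is.na(samples$o2)
  x <- samples$o2[ok]; y <- samples$fe_cu_ratio[ok]
  if (length(x) < 2) stop("need at least 2 complete (ratio, O2) pairs")
  if (stats::var(x) == 0) stop("degenerate design: all O2 values identical")
  fit <- stats::lm(y ~ x)
  # exact-line input is legitimate here; silence summary.lm's
  # "essentially perfect fit" note
  r2 <- if (stats::var(y) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope)) slope <- 0
  linear_fit(slope, unname(stats::coef(fit)[1]), r2, length(x))
}

#' Predicted maximum Fe:Cu ratio at zero oxygen
#'
#' Evaluates a linear Fe:Cu-vs-O2 fit in the zero-oxygen limit, i.e.
#' returns the intercept. For a negative slope this is the predicted
#' maximum ratio; for a nonnegative slope the value is still returned
#' but flagged (attribute `is_maximum = FALSE`).
#'
#' @param fit A `LinearFit`.
#' @return The predicted ratio at O2 = 0 (numeric scalar with attribute
#'   `is_maximum`).
#' @export
predict_zero_oxygen <- function(fit) {
  stopifnot(inherits(fit, "LinearFit"))
  out <- fit$intercept
  attr(out, "is_maximum") <- fit$slope < 0
  if (fit$slope >= 0)
    warning("nonnegative slope: zero-O2 value is not a predicted maximum")
  out
}

# all permutations of 1..n, one per row (n! x n matrix)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1):(r + nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is Pearson correlation on mid-ranks (ties averaged). The
#' two-sided p-value uses the t approximation with n-2 degrees of
#' freedom for n >= 10 and full permutation enumeration of one margin
#' for n < 10.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); pairs with any
#'   NA are dropped.
#' @return List with rho, p_value, n, method.
#' @export
spearman_rho_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant vector: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  } else {
    P <- .all_perms(n)
    mx <- mean(rx); sx <- stats::sd(rx)
    my <- mean(ry); sy <- stats::sd(ry)
    # rho for every permutation of the x-ranks against fixed y-ranks
    S <- matrix(rx[P], nrow(P), n) %*% ry
    rho_all <- (S / (n - 1) - n * mx * my / (n - 1)) / (sx * sy)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

#' Spearman screen of inventory labels against environmental variables
#'
#' Correlates every inventory column with every geochemistry column over
#' samples present in both, using pairwise-complete observations.
#' Benjamini-Hochberg q-values are computed across the whole screen;
#' no correction is applied to the primary p-values.
#'
#' @param inventory Samples x labels numeric matrix (e.g. per-100k
#'   values), rownames = sample ids.
#' @param geochem Samples x variables numeric matrix or data frame,
#'   rownames/sample_id matching `inventory`.
#' @param min_n Minimum complete pairs per test.
#' @return Data frame (x_name, y_name, rho, p_value, q_value, n, note);
#'   pairs skipped for constant input or insufficient n carry a note and
#'   NA statistics.
#' @export
spearman_screen <- function(inventory, geochem, min_n = 3L) {
  if (is.data.frame(geochem)) {
    if (!is.null(geochem$sample_id)) {
      rownames(geochem) <- geochem$sample_id
      geochem <- geochem[, setdiff(names(geochem),
                                   c("sample_id", "zone")), drop = FALSE]
    }
    geochem <- as.matrix(geochem[vapply(geochem, is.numeric, TRUE)])
  }
  common <- intersect(rownames(inventory), rownames(geochem))
  if (length(common) < min_n) stop("fewer than min_n shared samples")
  inv <- inventory[common, , drop = FALSE]
  geo <- geochem[common, , drop = FALSE]
  rows <- list()
  for (lab in colnames(inv)) for (v in colnames(geo)) {
    x <- geo[, v]; y <- inv[, lab]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_n) {
      rows[[length(rows) + 1]] <- data.frame(
        x_name = v, y_name = lab, rho = NA_real_, p_value = NA_real_,
        n = sum(ok), note = "insufficient pairs", stringsAsFactors = FALSE)
      next
    }
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        x_name = v, y_name = lab, rho = NA_real_, p_value = NA_real_,
        n = sum(ok), note = "constant vector", stringsAsFactors = FALSE)
      next
    }
    r <- spearman_rho_p(x[ok], y[ok])
    rows[[length(rows) + 1]] <- data.frame(
      x_name = v, y_name = lab, rho = r$rho, p_value = r$p_value,
      n = r$n, note = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], "BH")
  out[, c("x_name", "y_name", "rho", "p_value", "q_value", "n", "note")]
}

#' Rarefy a count matrix by repeated subsampling
#'
#' Each sample (row) is subsampled without replacement to `depth`,
#' `reps` times; the per-label mean over repetitions is returned.
#'
#' @param counts Samples x labels nonnegative integer matrix.
#' @param depth Target depth; must not exceed any sample's total.
#' @param reps Number of subsampling repetitions (default 999).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @return Numeric matrix of expected rarefied counts.
#' @export
rarefy_matrix <- function(counts, depth, reps = 999L, seed = 1L) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  low <- totals < depth
  if (any(low))
    stop("rarefaction depth ", depth, " exceeds total of sample(s): ",
         paste(rownames(counts)[low], collapse = ", "))
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)
  acc <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (r in seq_len(reps)) {
    # rrarefy's small-count heuristic warning is irrelevant here: inputs
    # are validated as true counts above
    acc <- acc + suppressWarnings(vegan::rrarefy(counts, depth))
  }
  acc / reps
}

#' Partial canonical correspondence analysis
#'
#' Constrained ordination of a chi-square-standardized community matrix
#' on environmental variables, optionally after partialling out
#' covariates (conditions). Computation is delegated to
#' \code{vegan::cca}; constant constraint columns are dropped with a
#' note (a constant has no span after centering, so alone it yields zero
#' constrained inertia), and non-constant collinear constraints raise an
#' error naming the aliased columns. Species scores use vegan's scaling
#' 2 (scaled by the square root of the eigenvalues).
#'
#' @param community Samples x labels nonnegative matrix with at least 3
#'   samples.
#' @param constraints Samples x variables numeric matrix/data frame.
#' @param conditions Optional samples x covariates matrix/data frame.
#' @return A `CcaResult`: eigenvalues_constrained,
#'   eigenvalues_unconstrained, total_inertia, constrained_inertia,
#'   site_scores, species_scores, biplot_scores, dropped_constraints,
#'   and the underlying vegan object in `fit`.
#' @export
partial_cca <- function(community, constraints, conditions = NULL) {
  community <- as.matrix(community)
  if (nrow(community) < 3) stop("need at least 3 samples")
  X <- as.matrix(as.data.frame(constraints))
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("env", seq_len(ncol(X)))
  cent <- scale(X, center = TRUE, scale = FALSE)
  const <- apply(cent, 2, function(c) all(abs(c) < 1e-12))
  dropped <- colnames(X)[const]
  X <- X[, !const, drop = FALSE]
  if (ncol(X) > 0) {
    q <- qr(scale(X, center = TRUE, scale = FALSE))
    if (q$rank < ncol(X)) {
      aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
      stop("rank-deficient constraints; collinear column(s): ",
           paste(aliased, collapse = ", "))
    }
  }
  if (ncol(X) == 0) {
    fit <- vegan::cca(community)
    res <- list(eigenvalues_constrained = numeric(0),
                eigenvalues_unconstrained = unname(fit$CA$eig),
                total_inertia = fit$tot.chi,
                constrained_inertia = 0,
                site_scores = vegan::scores(fit, display = "sites",
                                            scaling = 2),
                species_scores = vegan::scores(fit, display = "species",
                                               scaling = 2),
                biplot_scores = NULL,
                dropped_constraints = dropped, fit = fit)
    class(res) <- "CcaResult"
    return(res)
  }
  fit <- if (is.null(conditions)) {
    vegan::cca(X = community, Y = X)
  } else {
    vegan::cca(X = community, Y = X, Z = as.matrix(conditions))
  }
  constrained <- if (is.null(fit$CCA)) numeric(0) else unname(fit$CCA$eig)
  sc <- vegan::scores(fit, display = c("sites", "species", "bp"),
                      scaling = 2)
  res <- list(eigenvalues_constrained = constrained,
              eigenvalues_unconstrained =
                if (is.null(fit$CA)) numeric(0) else unname(fit$CA$eig),
              total_inertia = fit$tot.chi,
              constrained_inertia = sum(constrained),
              site_scores = sc$sites,
              species_scores = sc$species,
              biplot_scores = sc$biplot,
              dropped_constraints = dropped, fit = fit)
  class(res) <- "CcaResult"
  res
}

#' @export
print.CcaResult <- function(x, ...) {
  cat("Partial CCA: total inertia", format(x$total_inertia, digits = 4),
      "| constrained", format(x$constrained_inertia, digits = 4), "(",
      length(x$eigenvalues_constrained), "axes )\n")
  if (length(x$dropped_constraints))
    cat("  dropped constant constraint(s):",
        paste(x$dropped_constraints, collapse = ", "), "\n")
  invisible(x)
}
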