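#' Binomial mixture models for bleaching-step histograms
#'
#' `binomial_pmf()` is the two-binomial model for homopentamer data: a spot
#' contains one complex (probability `A`, label order `n`) or two
#' (probability `1 - A`, order `2n`), and each label is mature and unbleached
#' with probability `p_m`, so the probability of observing `x` steps is
#' \deqn{B(x) = A \, \mathrm{Bin}(x; n, p_m) +
#'       (1 - A) \, \mathrm{Bin}(x; 2n, p_m).}
#' `binomial_mixture_pmf()` extends this to co-expression data as a mixture
#' of a homopentamer branch (order `n`) with weight `H` and a heteropentamer
#' branch (label order `het`) with weight `1 - H`, each branch itself the
#' two-binomial spot model above.
#'
#' @param x Integer step counts (vectorized).
#' @param n Homopentamer label order (default 5).
#' @param p_m Maturation probability.
#' @param A Single-complex spot fraction.
#' @param H Homopentamer fraction.
#' @param het Heteropentamer label order (1..n).
#' @param renormalize If `TRUE`, renormalize over the observable support
#'   `x >= 1` (spots with zero mature labels are undetectable).
#' @return Probabilities at `x`.
#' @examples
#' sum(binomial_pmf(0:10, p_m = 0.47, A = 0.88))  # 1
#' @export
binomial_pmf <- function(x, n = 5L, p_m, A, renormalize = FALSE) {
  p <- A * dbinom(x, n, p_m) + (1 - A) * dbinom(x, 2L * n, p_m)
  if (renormalize) {
    p0 <- A * dbinom(0L, n, p_m) + (1 - A) * dbinom(0L, 2L * n, p_m)
    p <- ifelse(x >= 1L, p / (1 - p0), 0)
  }
  p
}

#' @rdname binomial_pmf
#' @export
binomial_mixture_pmf <- function(x, n = 5L, het = 3L, p_m, A, H,
                                 renormalize = FALSE) {
  p <- H * binomial_pmf(x, n, p_m, A) +
    (1 - H) * binomial_pmf(x, het, p_m, A)
  if (renormalize) {
    p0 <- H * binomial_pmf(0L, n, p_m, A) +
      (1 - H) * binomial_pmf(0L, het, p_m, A)
    p <- ifelse(x >= 1L, p / (1 - p0), 0)
  }
  p
}

#' Aggregate accepted step counts into a histogram
#'
#' Spots are grouped by their cell/field identifier; fields whose fraction of
#' accepted traces falls below `min_accept_fraction` are dropped entirely
#' (too few accepted traces indicate unreliable data), and the remaining
#' accepted counts are aggregated.
#'
#' @param steps Integer vector of accepted step counts (`NA` for rejected
#'   spots).
#' @param field Field/cell identifier per spot (defaults to one field).
#' @param min_accept_fraction Minimum accepted/total fraction per field
#'   (default 0.10).
#' @return An object of class `step_histogram` with `counts` (named vector
#'   over `x = 1..max`), `total`, `n_rejected` and `fields_dropped`.
#' @export
build_histogram <- function(steps, field = rep(1L, length(steps)),
                            min_accept_fraction = 0.10) {
  stopifnot(length(steps) == length(field))
  keep_field <- tapply(!is.na(steps) & steps > 0L, field, mean)
  dropped <- names(keep_field)[keep_field < min_accept_fraction]
  use <- !(as.character(field) %in% dropped) & !is.na(steps) & steps > 0L
  x <- steps[use]
  counts <- if (length(x)) {
    tab <- tabulate(x, nbins = max(x))
    setNames(tab, seq_along(tab))
  } else setNames(integer(0), character(0))
  out <- structure(list(counts = counts, total = sum(counts),
                        n_rejected = sum(is.na(steps) | steps == 0L),
                        fields_dropped = dropped),
                   class = "step_histogram")
  if (out$total == 0L) warning("empty step histogram")
  out
}

#' @export
print.step_histogram <- function(x, ...) {
  cat(sprintf("<step_histogram> %d accepted spots, %d rejected, %d field(s) dropped\n",
              x$total, x$n_rejected, length(x$fields_dropped)))
  if (x$total) print(x$counts)
  invisible(x)
}

#' Fit a binomial step-count model to a step histogram
#'
#' Maximum-likelihood fit (multinomial likelihood over the observable
#' support `x >= 1`) of the model pmf to the observed bin counts; the
#' likelihood weights bins by their information content, which matters at
#' the few-hundred-spot sample sizes typical here. Goodness of fit is the
#' chi-squared statistic over occupied bins with degrees of freedom
#' `occupied bins - free parameters - 1`; a fit is adequate when the
#' chi-squared p-value exceeds 0.05. With `model = "mixture"`, all four
#' heteromer label orders 1..4 can be scanned and ranked by p-value via
#' [scan_heteromer_orders()].
#'
#' @param hist A [build_histogram()] result, or a named integer vector of
#'   counts over `x = 1..max`.
#' @param model `"homo"` fits the two-binomial model (free: `p_m`, `A`);
#'   `"mixture"` fits the homo/hetero mixture (free: `H`; `p_m`, `A`, `het`
#'   fixed).
#' @param n Homopentamer label order.
#' @param het Heteromer label order (mixture model).
#' @param p_m,A,H Starting values (free parameters) or fixed values.
#' @param free Character vector naming the free parameters; defaults to
#'   `c("p_m", "A")` for `"homo"` and `"H"` for `"mixture"`.
#' @return An object of class `binomial_fit` with the parameter estimates,
#'   `chisq`, `df`, `p_value`, `expected` counts and the model spec.
#' @export
fit_binomial <- function(hist, model = c("homo", "mixture"), n = 5L,
                         het = 3L, p_m = 0.5, A = 0.9, H = 0.5,
                         free = NULL) {
  model <- match.arg(model)
  counts <- if (inherits(hist, "step_histogram")) hist$counts else hist
  if (!length(counts) || sum(counts) == 0L) stop("empty histogram")
  x <- as.integer(names(counts))
  if (any(is.na(x))) x <- seq_along(counts)
  total <- sum(counts)
  free <- free %||% if (model == "homo") c("p_m", "A") else "H"
  params <- list(p_m = p_m, A = A, H = H)
  if (length(free) >= sum(counts > 0))
    stop("free parameters must be fewer than occupied bins")
  pmf <- function(pars) {
    p <- modifyList(params, as.list(pars))
    if (model == "homo")
      binomial_pmf(x, n, p$p_m, p$A, renormalize = TRUE)
    else
      binomial_mixture_pmf(x, n, het, p$p_m, p$A, p$H, renormalize = TRUE)
  }
  obj <- function(v) {
    pars <- setNames(as.list(v), free)
    -sum(counts * log(pmax(pmf(pars), 1e-300)))
  }
  lower <- rep(1e-6, length(free))
  upper <- rep(1 - 1e-6, length(free))
  start <- unlist(params[free])
  opt <- optim(start, obj, method = "L-BFGS-B", lower = lower,
               upper = upper)
  est <- modifyList(params, as.list(setNames(opt$par, free)))
  expected <- total * pmf(setNames(as.list(opt$par), free))
  occ <- counts > 0
  chisq <- sum((counts[occ] - expected[occ])^2 / expected[occ])
  df <- sum(occ) - length(free) - 1L
  p_value <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  structure(list(model = model, n = n, het = if (model == "mixture") het,
                 p_m = est$p_m, A = est$A,
                 H = if (model == "mixture") est$H,
                 free = free, chisq = chisq, df = df, p_value = p_value,
                 expected = expected, observed = counts, x = x,
                 converged = opt$convergence == 0),
            class = "binomial_fit")
}

#' @export
print.binomial_fit <- function(x, ...) {
  if (x$model == "homo") {
    cat(sprintf("<binomial_fit> homo: p_m = %.3f, A = %.3f", x$p_m, x$A))
  } else {
    cat(sprintf("<binomial_fit> mixture het=%d: H = %.3f (heteromer %.1f%%)",
                x$het, x$H, 100 * (1 - x$H)))
  }
  cat(sprintf("  [chi^2 = %.2f, df = %d, p = %.3f]\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Scan heteromer label orders and rank fits by goodness of fit
#'
#' Fits the homo/hetero mixture model at every heteromer label order in
#' `orders` (with `p_m` and `A` fixed and `H` free) and ranks the fits by
#' chi-squared p-value. Neighboring orders often fit acceptably too; with
#' fewer than ten occupied bins several good fits are expected.
#'
#' @inheritParams fit_binomial
#' @param orders Heteromer label orders to scan.
#' @return A list of [fit_binomial()] results ordered by decreasing
#'   p-value, with the scan table attached as attribute `"ranking"`.
#' @export
scan_heteromer_orders <- function(hist, n = 5L, orders = 1:4, p_m, A,
                                  H = 0.5) {
  fits <- lapply(orders, function(h)
    fit_binomial(hist, "mixture", n = n, het = h, p_m = p_m, A = A, H = H))
  pv <- vapply(fits, function(f) f$p_value, numeric(1))
  ord <- order(pv, decreasing = TRUE)
  ranking <- data.frame(het = orders[ord], p_value = pv[ord],
                        H = vapply(fits, function(f) f$H, numeric(1))[ord])
  out <- fits[ord]
  attr(out, "ranking") <- ranking
  out
}
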