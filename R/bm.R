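## Maximum-likelihood Brownian-motion clade models on a two-clade tree
## whose root is the clade split (outgroup removed).  Four models: clade
## means shared or separate, crossed with Brownian rates shared or
## separate.  Clade A's rate applies to every edge inside clade A
## *including its stem*, so stem-branch scaling is operative on the
## likelihood.  Means are profiled out by GLS, the Brownian variance has a
## closed-form ML estimate, and the single free rate ratio (when present)
## is optimized on a log scale.

.BM_MODELS <- c("same_mean_same_rate", "diff_mean_same_rate",
                "same_mean_diff_rate", "diff_mean_diff_rate")
.BM_NPAR <- c(same_mean_same_rate = 2L, diff_mean_same_rate = 3L,
              same_mean_diff_rate = 3L, diff_mean_diff_rate = 4L)

#' Define the two-clade split
#'
#' @param clade_a_tips,clade_b_tips disjoint tip label sets whose union is
#'   all tips; each side must be one of the root's two subtrees
#' @return object of class `clade_split`
#' @export
clade_split <- function(clade_a_tips, clade_b_tips) {
  if (length(intersect(clade_a_tips, clade_b_tips)))
    stop("clade error: overlapping tip sets")
  structure(list(a = clade_a_tips, b = clade_b_tips), class = "clade_split")
}

.check_split <- function(tree, split) {
  n <- length(tree$tip.label)
  if (!setequal(c(split$a, split$b), tree$tip.label))
    stop("clade error: split does not cover all tips")
  root_children <- tree$edge[tree$edge[, 1] == n + 1L, 2]
  if (length(root_children) != 2L)
    stop("clade error: root must be the binary A/B split")
  tipset <- function(node) {
    if (node <= n) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
  }
  s1 <- tipset(root_children[1])
  if (!(setequal(s1, split$a) || setequal(s1, split$b)))
    stop("clade error: root does not separate the two clades")
  invisible(TRUE)
}

## Relative (sigma2-free) trait covariance among tips, with clade-A edges
## (stem included) scaled by rel_rate_a.  Block diagonal across clades
## because the root is the split.
.bm_rel_cov <- function(tree, split, rel_rate_a) {
  n <- length(tree$tip.label)
  scaled <- tree
  in_a <- .edges_in_clade(tree, split$a)
  scaled$edge.length[in_a] <- scaled$edge.length[in_a] * rel_rate_a
  V <- ape::vcv(scaled)
  V[tree$tip.label, tree$tip.label]
}

## Edge indices whose descendant tips are all in `tips` (includes the stem
## edge of the clade's MRCA).
.edges_in_clade <- function(tree, tips) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  inset <- logical(n + tree$Nnode)
  inset[match(tips, tree$tip.label)] <- TRUE
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (node in unique(po$edge[, 1]))
    inset[node] <- all(inset[kids[[as.character(node)]]])
  which(inset[tree$edge[, 2]])
}

## Cholesky with a minimal ridge fallback: tied tips (zero-length NJ
## edges) make the BM covariance exactly singular; a diagonal ridge of
## 1e-10 x mean diagonal (grown as needed) restores definiteness with a
## negligible likelihood perturbation.
.chol_safe <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  eps <- 1e-10 * mean(diag(V))
  while (is.null(ch) && eps < mean(diag(V))) {
    ch <- tryCatch(chol(V + diag(eps, nrow(V))), error = function(e) NULL)
    eps <- eps * 10
  }
  if (is.null(ch)) stop("fit error: covariance matrix not positive definite")
  ch
}

.check_clade_ultrametric <- function(tree, split, tol_rel = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  d <- depths[seq_len(n)]
  names(d) <- tree$tip.label
  for (tips in list(split$a, split$b)) {
    dd <- d[tips]
    if (diff(range(dd)) > tol_rel * max(max(dd), 1))
      stop("shape error: tree not ultrametric within clade (tolerance ",
           tol_rel, " x depth)")
  }
  invisible(TRUE)
}

#' Brownian-motion log-likelihood for clade means/rates
#'
#' Multivariate-normal log-likelihood of tip values with expectation equal
#' to the tip's clade mean (or a shared mean) and covariance
#' `sigma2 * shared path length`, clade-A edges (stem included) scaled by
#' `rel_rate_a`.
#'
#' @param tree rooted `phylo`, root = clade split, ultrametric within each
#'   clade (tolerance `1e-6 * depth`)
#' @param values named numeric vector of tip trait values
#' @param split a [clade_split()]
#' @param mu length-1 (shared) or length-2 `c(mu_a, mu_b)` mean(s)
#' @param sigma2 Brownian variance (> 0), on the clade-B rate scale
#' @param rel_rate_a rate of clade A relative to clade B (> 0)
#' @return log-likelihood
#' @export
bm_loglik <- function(tree, values, split, mu, sigma2, rel_rate_a = 1) {
  stopifnot(sigma2 > 0, rel_rate_a > 0)
  .check_split(tree, split)
  .check_clade_ultrametric(tree, split)
  x <- values[tree$tip.label]
  if (anyNA(x)) stop("labeling error: missing trait values")
  V <- .bm_rel_cov(tree, split, rel_rate_a) * sigma2
  m <- if (length(mu) == 2L)
    ifelse(tree$tip.label %in% split$a, mu[1], mu[2]) else rep(mu, length(x))
  ch <- .chol_safe(V)
  z <- backsolve(ch, x - m, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

## GLS fit at fixed relative rate: returns means, ML sigma2 and lnL.
.bm_profile <- function(tree, values, split, diff_mean, rel_rate_a) {
  x <- values[tree$tip.label]
  V0 <- .bm_rel_cov(tree, split, rel_rate_a)
  ch <- .chol_safe(V0)
  X <- if (diff_mean)
    cbind(a = as.numeric(tree$tip.label %in% split$a),
          b = as.numeric(tree$tip.label %in% split$b))
  else cbind(mu = rep(1, length(x)))
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, x, transpose = TRUE)
  fit <- qr.solve(Xi, yi)
  resid <- yi - Xi %*% fit
  nn <- length(x)
  s2 <- sum(resid^2) / nn
  lnL <- -0.5 * (nn * log(2 * pi) + nn * log(s2) +
                   2 * sum(log(diag(ch))) + nn)
  list(mu = as.numeric(fit), sigma2 = s2, lnL = lnL)
}

#' Fit one Brownian-motion clade model by maximum likelihood
#'
#' @inheritParams bm_loglik
#' @param model one of `"same_mean_same_rate"`, `"diff_mean_same_rate"`,
#'   `"same_mean_diff_rate"`, `"diff_mean_diff_rate"`
#' @return object of class `bm_fit`: list with `model`, `mu` (named, per
#'   clade where separate), `sigma2` (clade-B scale), `sigma2_a` (clade-A
#'   scale, `sigma2 * rel_rate_a`), `rel_rate_a`, `lnL`, `n_params`, `aic`
#' @export
bm_fit <- function(tree, values, split, model = .BM_MODELS) {
  model <- match.arg(model)
  .check_split(tree, split)
  .check_clade_ultrametric(tree, split)
  diff_mean <- model %in% c("diff_mean_same_rate", "diff_mean_diff_rate")
  diff_rate <- model %in% c("same_mean_diff_rate", "diff_mean_diff_rate")
  if (diff_rate) {
    obj <- function(logr) .bm_profile(tree, values, split, diff_mean,
                                      exp(logr))$lnL
    opt <- optimize(obj, c(log(1e-4), log(1e4)), maximum = TRUE,
                    tol = 1e-10)
    r <- exp(opt$maximum)
  } else r <- 1
  pf <- .bm_profile(tree, values, split, diff_mean, r)
  npar <- .BM_NPAR[[model]]
  mu <- if (diff_mean) setNames(pf$mu, c("mu_a", "mu_b"))
        else setNames(pf$mu, "mu")
  structure(list(model = model, mu = mu, sigma2 = pf$sigma2,
                 sigma2_a = pf$sigma2 * r, rel_rate_a = r,
                 lnL = pf$lnL, n_params = npar,
                 aic = 2 * npar - 2 * pf$lnL),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("bm_fit [%s]: lnL=%.4f AIC=%.4f sigma2=%.4g rel_rate_a=%.3g\n",
              x$model, x$lnL, x$aic, x$sigma2, x$rel_rate_a))
  cat("means:", paste(sprintf("%s=%.4f", names(x$mu), x$mu), collapse = " "),
      "\n")
  invisible(x)
}

#' Four-model Brownian-motion comparison with stem-branch sensitivity
#'
#' For each stem factor, scales clade A's stem branch via
#' [scale_clade_stem()], refits all four mean/rate models and flags the
#' AIC-minimal model per factor.
#'
#' @inheritParams bm_loglik
#' @param stem_factors multipliers applied to the clade-A stem
#'   (default `c(1, 0.5)`: full-length and halved)
#' @return data.frame: model, stem_factor, lnL, aic, sigma2, sigma2_a,
#'   rel_rate_a, mu_a, mu_b, best (logical)
#' @export
clade_model_table <- function(tree, values, split, stem_factors = c(1, 0.5)) {
  rows <- list()
  for (f in stem_factors) {
    tf <- scale_clade_stem(tree, split$a, f)
    fits <- lapply(.BM_MODELS, function(m) bm_fit(tf, values, split, m))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    for (i in seq_along(fits)) {
      ft <- fits[[i]]
      mu2 <- if (length(ft$mu) == 2L) ft$mu else rep(ft$mu, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        model = ft$model, stem_factor = f, lnL = ft$lnL, aic = ft$aic,
        sigma2 = ft$sigma2, sigma2_a = ft$sigma2_a,
        rel_rate_a = ft$rel_rate_a,
        mu_a = mu2[[1]], mu_b = mu2[[2]],
        best = i == which.min(aics))
    }
  }
  do.call(rbind, rows)
}
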