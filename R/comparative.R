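#' Ordinary least-squares residuals against covariates
#'
#' Residualizes a trait on one or more covariates plus an intercept. Used
#' to control (log-) lifespan and DR counts for (log-) body mass before
#' phylogenetic contrasts are taken.
#'
#' @param y numeric trait vector
#' @param X numeric vector or matrix of covariates (no intercept column;
#'   one is added)
#' @return residual vector, orthogonal to the intercept and each covariate
#' @export
residualize <- function(y, X) {
  X <- as.matrix(X)
  if (anyNA(y) || anyNA(X)) stop("missing values not allowed")
  if (nrow(X) != length(y)) stop("y and X dimensions disagree")
  # constant covariates are absorbed by the intercept
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  M <- cbind(1, X[, keep, drop = FALSE])
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) stop("collinear covariates")
  unname(stats::lm.fit(M, y)$residuals)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node of a rooted
#' binary tree the standardized contrast is
#' (x_left - x_right) / sqrt(v_left + v_right), where v are the (possibly
#' extended) branch lengths below the node; the node's ancestral value is
#' the branch-length-weighted average of its daughters and its own parent
#' branch is extended by v_left * v_right / (v_left + v_right).
#'
#' Zero-length branches (e.g. from resolving polytomies) are replaced by
#' 1e-8 times the tree height, with a message.
#'
#' @param tree rooted binary `phylo` tree with branch lengths
#' @param trait named numeric vector of leaf values (names must cover the
#'   tree's tip labels)
#' @return numeric vector of n-1 standardized contrasts, named by internal
#'   node number, in increasing node-number order
#' @export
independent_contrasts <- function(tree, trait) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.binary(tree)) stop("tree must be fully bifurcating")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least two leaves")
  if (is.null(names(trait))) {
    if (length(trait) != ntip) stop("unnamed trait must have one value per tip")
    names(trait) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) {
    stop("leaf without trait value: ", paste(miss, collapse = ", "))
  }
  if (anyNA(trait[tree$tip.label])) stop("leaf without trait value (NA)")

  el <- tree$edge.length
  if (any(el < 0)) stop("negative branch length")
  if (any(el == 0)) {
    h <- max(ape::node.depth.edgelength(tree))
    el[el == 0] <- 1e-8 * h
    message("replaced ", sum(tree$edge.length == 0),
            " zero-length branch(es) by 1e-8 x tree height")
  }

  nnode <- tree$Nnode
  x <- numeric(ntip + nnode)
  v <- numeric(ntip + nnode)
  x[seq_len(ntip)] <- trait[tree$tip.label]
  contrasts <- numeric(nnode)

  # postorder sweep: children are resolved before their parent
  ord <- ape::reorder.phylo(tree, "postorder")
  # map reordered edges back onto the stored edge lengths
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  el_post <- el[match(paste(ord$edge[, 1], ord$edge[, 2]), key)]
  parents <- unique(ord$edge[, 1])
  for (node in parents) {
    rows <- which(ord$edge[, 1] == node)
    if (length(rows) != 2L) stop("non-binary node ", node)
    ch <- ord$edge[rows, 2]
    bl <- el_post[rows] + v[ch]
    if (sum(bl) <= 0) stop("zero pooled variance at node ", node)
    contrasts[node - ntip] <- (x[ch[1]] - x[ch[2]]) / sqrt(sum(bl))
    x[node] <- (bl[2] * x[ch[1]] + bl[1] * x[ch[2]]) / sum(bl)
    v[node] <- prod(bl) / sum(bl)
  }
  stats::setNames(contrasts, ntip + seq_len(nnode))
}

#' Correlation of two contrast sets
#'
#' Product-moment correlation constrained through the origin (the standard
#' treatment for independent contrasts, whose signs are arbitrary):
#' rho = sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2)), with a t-test on
#' k - 1 degrees of freedom for k contrasts.
#'
#' @param cx,cy contrast vectors from the same tree, same node order
#' @param alternative "two.sided", "less" or "greater"
#' @param through_origin set FALSE to use the ordinary (centred)
#'   correlation, for sensitivity analysis only
#' @param control optional contrast vector or matrix of control variables;
#'   both `cx` and `cy` are projected (through the origin) onto the
#'   orthogonal complement of the controls before correlating, giving a
#'   contrast-level partial correlation. This is the alternative to
#'   residualizing traits at the leaves before taking contrasts; one
#'   degree of freedom is spent per control column.
#' @return list with `rho`, `p`, `df`
#' @export
contrast_correlation <- function(cx, cy,
                                 alternative = c("two.sided", "less", "greater"),
                                 through_origin = TRUE, control = NULL) {
  alternative <- match.arg(alternative)
  if (length(cx) != length(cy)) stop("contrast sets differ in length")
  k <- length(cx)
  if (k < 3L) stop("need at least 3 contrasts")
  n_ctrl <- 0L
  if (!is.null(control)) {
    C <- as.matrix(control)
    if (nrow(C) != k) stop("control contrasts differ in length")
    n_ctrl <- ncol(C)
    proj <- C %*% solve(crossprod(C), crossprod(C, cbind(cx, cy)))
    cx <- cx - proj[, 1]
    cy <- cy - proj[, 2]
  }
  if (!through_origin) {
    cx <- cx - mean(cx)
    cy <- cy - mean(cy)
  }
  sx2 <- sum(cx^2)
  sy2 <- sum(cy^2)
  if (sx2 == 0 || sy2 == 0) stop("zero variance in contrasts")
  rho <- sum(cx * cy) / sqrt(sx2 * sy2)
  df <- k - 1L - n_ctrl
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              less = stats::pt(tstat, df),
              greater = stats::pt(tstat, df, lower.tail = FALSE))
  list(rho = rho, p = p, df = df)
}

#' Short- vs long-lived subpopulation tests
#'
#' Splits species at a lifespan percentile (ties go to the short-lived
#' group) and compares a count column between the two groups with a
#' two-sample t-test (means), Mann-Whitney U test (medians; exact for
#' small samples without ties, normal approximation with tie correction
#' otherwise) and two-sample Kolmogorov-Smirnov test (distributions).
#'
#' @param records data.frame with a `lifespan` column and the value column
#' @param percentile lifespan percentile for the split (e.g. 50, 75, 90)
#' @param value name of the column compared (e.g. a long-DR count)
#' @param alternative passed to the three tests; for one-sided tests the
#'   alternative refers to the short-lived group relative to the long-lived
#'   group (e.g. "greater" tests short > long)
#' @return list with `threshold`, group sizes, and `t`, `mwu`, `ks`
#'   sublists of statistic and p-value
#' @export
subpopulation_tests <- function(records, percentile = 50,
                                value = "dr_count",
                                alternative = "two.sided") {
  if (!value %in% names(records)) stop("no column '", value, "'")
  thr <- stats::quantile(records$lifespan, percentile / 100, names = FALSE)
  short <- records[[value]][records$lifespan <= thr]
  long <- records[[value]][records$lifespan > thr]
  if (!length(short) || !length(long)) {
    stop("empty subpopulation at percentile ", percentile)
  }
  tt <- stats::t.test(short, long, alternative = alternative)
  exact <- max(length(short), length(long)) <= 20 &&
    !any(duplicated(c(short, long)))
  mwu <- stats::wilcox.test(short, long, alternative = alternative,
                            exact = exact, correct = TRUE)
  ks <- suppressWarnings(stats::ks.test(short, long,
                                        alternative = alternative))
  list(threshold = thr, n_short = length(short), n_long = length(long),
       t = list(statistic = unname(tt$statistic), p = tt$p.value),
       mwu = list(statistic = unname(mwu$statistic), p = mwu$p.value),
       ks = list(statistic = unname(ks$statistic), p = ks$p.value))
}

#' Z-test of a native count against a null ensemble
#'
#' z = (native - ensemble mean) / ensemble sd, with a normal p-value.
#'
#' @param native_count observed count on the native sequence
#' @param ensemble `null_ensemble`, or a list with `mean` and `sd`
#' @param alternative "two.sided", "less" or "greater" (native vs null)
#' @return list with `z`, `p`
#' @export
ensemble_z_test <- function(native_count, ensemble,
                            alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(ensemble$sd) || is.na(ensemble$sd) || ensemble$sd <= 0) {
    stop("ensemble standard deviation must be positive")
  }
  z <- (native_count - ensemble$mean) / ensemble$sd
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(z = z, p = p)
}

#' Upper constraint line through chosen support points
#'
#' Ordinary least squares fitted to a hand-picked set of support species
#' (with optional exclusions), as used to draw an upper limit of long-DR
#' count versus lifespan; all points above the fitted line are flagged.
#'
#' @param points data.frame with columns `id`, `x`, `y`
#' @param support ids of the species defining the line
#' @param exclude ids removed from the support set before fitting
#' @return list with `slope`, `intercept`, and `above` (ids of points
#'   strictly above the line)
#' @export
constraint_line <- function(points, support, exclude = character(0)) {
  support <- setdiff(support, exclude)
  sp <- points[points$id %in% support, , drop = FALSE]
  if (nrow(sp) < 2L) stop("need at least 2 support points")
  fit <- stats::lm(y ~ x, data = sp)
  co <- stats::coef(fit)
  pred <- co[1] + co[2] * points$x
  list(slope = unname(co[2]), intercept = unname(co[1]),
       above = points$id[points$y > pred + 1e-12])
}

#' Pairwise Mann-Whitney tests among taxonomic orders
#'
#' For each pair of groups, compares the values with a Mann-Whitney U
#' test. Raw p-values are reported without multiplicity correction.
#' Degenerate pairs (a group with fewer than 2 members, or both groups
#' constant at the same value) are left NA.
#'
#' @param values numeric vector (e.g. DR counts at one size)
#' @param groups factor or character vector of group labels
#' @param alternative "two.sided", "less" or "greater"
#' @return symmetric (for two-sided) matrix of p-values, groups x groups
#' @export
group_pairwise_tests <- function(values, groups,
                                 alternative = "two.sided") {
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need at least 2 groups")
  P <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (i == j) next
      a <- values[groups == lv[i]]
      b <- values[groups == lv[j]]
      if (length(a) < 2L || length(b) < 2L) next
      if (length(unique(c(a, b))) == 1L) next
      w <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = alternative, exact = FALSE,
                           correct = TRUE))
      P[i, j] <- w$p.value
    }
  }
  P
}
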