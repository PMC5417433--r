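#' Variance-stabilizing transforms and the analyte registry
#'
#' `apply_transform()` applies one of the registered transforms elementwise;
#' `transform_registry()` maps each response analysed in the pipeline to the
#' transform used for it: trap counts and 4-allylanisole concentrations are
#' square-root transformed; the concentrations of beta-pinene, 3-carene,
#' myrcene, limonene, beta-phellandrene and camphene are log(y+1)
#' transformed; alpha-pinene is analysed untransformed.
#'
#' @param values numeric vector (non-negative for `sqrt`/`log1p`).
#' @param transform `"identity"`, `"sqrt"` or `"log1p"`.
#' @return transformed numeric vector; for `transform_registry()`, a named
#'   character vector analyte -> transform.
#' @examples
#' apply_transform(c(0, 9), "log1p")
#' transform_registry()["trap_count"]
#' @export
apply_transform <- function(values, transform = c("identity", "sqrt",
                                                  "log1p")) {
  transform <- match.arg(transform)
  if (transform != "identity" && any(values < 0, na.rm = TRUE))
    stop("negative values cannot be ", transform, "-transformed")
  switch(transform,
         identity = values,
         sqrt = sqrt(values),
         log1p = log1p(values))
}

#' @rdname apply_transform
#' @export
transform_registry <- function() {
  c(trap_count = "sqrt",
    "alpha-pinene" = "identity",
    "4-allylanisole" = "sqrt",
    "beta-pinene" = "log1p",
    "3-carene" = "log1p",
    myrcene = "log1p",
    limonene = "log1p",
    "beta-phellandrene" = "log1p",
    camphene = "log1p")
}

new_anova_fit <- function(F, df_num, df_den, ms_between, ms_within,
                          means, ns, transform = "identity",
                          method = "oneway") {
  structure(list(
    F = F, df_num = df_num, df_den = df_den,
    p_value = stats::pf(F, df_num, df_den, lower.tail = FALSE),
    ms_between = ms_between, ms_within = ms_within,
    means = means, ns = ns,
    transform_applied = transform, method = method), class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("%s ANOVA (%s response): F_%d,%d = %.4g, P = %.4g\n",
              x$method, x$transform_applied, x$df_num, x$df_den, x$F,
              x$p_value))
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' Classical between/within decomposition over a named list of group value
#' vectors; group means and sizes are retained for the protected-LSD step.
#'
#' @param groups named list of numeric vectors, one per group.
#' @param transform optional transform name applied to every value first.
#' @return object of class `anova_fit`: `F`, `df_num`, `df_den`, `p_value`,
#'   `ms_between`, `ms_within`, group `means` and `ns`.
#' @examples
#' oneway_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # F = 13.5 on (1, 4)
#' @export
oneway_anova <- function(groups, transform = "identity") {
  stopifnot(is.list(groups), length(groups) >= 2L,
            !is.null(names(groups)))
  groups <- lapply(groups, apply_transform, transform = transform)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(y) - length(groups) < 1L) stop("zero residual degrees of freedom")
  tab <- stats::anova(stats::lm(y ~ g))
  new_anova_fit(F = tab$`F value`[1],
                df_num = tab$Df[1], df_den = tab$Df[2],
                ms_between = tab$`Mean Sq`[1], ms_within = tab$`Mean Sq`[2],
                means = vapply(groups, mean, numeric(1)),
                ns = lengths(groups), transform = transform,
                method = "oneway")
}

#' One-way ANOVA reconstructed from group means and SEs
#'
#' Rebuilds the balanced one-way ANOVA from printed summary statistics: with
#' k groups of n each, \eqn{MS_B = n \sum_i (m_i - \bar m)^2 / (k-1)} and
#' \eqn{MS_W} is the mean within-group variance, recovered from the standard
#' errors as \eqn{n \cdot se_i^2}. Equivalent to [oneway_anova()] on the raw
#' data whenever the summaries came from a balanced dataset. This is how a
#' published table of means (SE) with n per group is turned back into its
#' omnibus F.
#'
#' @param means,ses numeric vectors of per-group means and standard errors.
#' @param n common per-group sample size (>= 2).
#' @param names optional group names.
#' @return an `anova_fit`.
#' @examples
#' fx <- fixture_tables()
#' t1 <- fx$table1[fx$table1$year == 2013, ]
#' anova_from_summary(t1$dbh_mean, t1$dbh_se, n = 4)  # F_5,18 = 1.46
#' @export
anova_from_summary <- function(means, ses, n, names = NULL) {
  k <- length(means)
  if (length(ses) != k) stop("means and ses must have equal length")
  if (k < 2L) stop("need at least two groups")
  if (n < 2L) stop("need n >= 2 per group")
  ms_between <- n * sum((means - mean(means))^2) / (k - 1)
  ms_within <- mean(n * ses^2)
  nm <- if (is.null(names)) paste0("g", seq_len(k)) else names
  new_anova_fit(F = ms_between / ms_within,
                df_num = as.integer(k - 1), df_den = as.integer(k * (n - 1)),
                ms_between = ms_between, ms_within = ms_within,
                means = stats::setNames(means, nm),
                ns = stats::setNames(rep.int(n, k), nm),
                method = "from_summary")
}

#' Randomized-block ANOVA with additive block effects
#'
#' Treatment F test from the residual after removing additive block effects
#' (site, week, ...). Blocks enter as fixed additive factors: with a
#' balanced design this yields the same treatment test as a mixed model with
#' random blocks, and the approximation is recorded in the result's
#' `method` field.
#'
#' @param records `data.frame` of observations.
#' @param response column name of the response.
#' @param treatment column name of the treatment factor.
#' @param blocks character vector of block factor column names (may be
#'   empty, in which case the fit reduces to a one-way ANOVA).
#' @param transform transform name applied to the response.
#' @return an `anova_fit` (marginal F for treatment, adjusted for blocks).
#' @export
blocked_anova <- function(records, response, treatment, blocks = character(),
                          transform = "identity") {
  stopifnot(is.data.frame(records),
            all(c(response, treatment, blocks) %in% names(records)))
  d <- records
  d$.y <- apply_transform(d[[response]], transform)
  d$.trt <- factor(d[[treatment]])
  if (nlevels(d$.trt) < 2L) stop("need at least two treatment levels")
  for (b in blocks) d[[b]] <- factor(d[[b]])
  rhs <- paste(c(blocks, ".trt"), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  if (stats::df.residual(fit) < 1L) stop("zero residual degrees of freedom")
  # sequential ANOVA with treatment last = treatment adjusted for blocks
  tab <- stats::anova(fit)
  i <- which(rownames(tab) == ".trt")
  new_anova_fit(F = tab$`F value`[i],
                df_num = tab$Df[i], df_den = stats::df.residual(fit),
                ms_between = tab$`Mean Sq`[i],
                ms_within = tab$`Mean Sq`[nrow(tab)],
                means = tapply(d$.y, d$.trt, mean),
                ns = stats::setNames(as.integer(table(d$.trt)),
                                     levels(d$.trt)),
                transform = transform,
                method = if (length(blocks)) "blocked" else "oneway")
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb letter assignment: groups sharing a letter are not
#' significantly different. Starts from a single letter covering all groups;
#' every significant pair splits each letter set containing both members,
#' and sets contained in another are absorbed. Letters are assigned greedily
#' in the matrix's row order (pass groups in descending-mean order for the
#' conventional display); the letter count is not guaranteed globally
#' minimal.
#'
#' @param sig symmetric logical matrix with group names as dimnames; `TRUE`
#'   means the pair differs significantly.
#' @return named character vector of letter strings.
#' @examples
#' m <- matrix(FALSE, 3, 3, dimnames = list(c("A","B","C"), c("A","B","C")))
#' m["A", "C"] <- m["C", "A"] <- TRUE
#' compact_letter_display(m)  # A "a", B "ab", C "b"
#' @export
compact_letter_display <- function(sig) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig))
  if (!isTRUE(all.equal(sig, t(sig)))) stop("significance matrix asymmetric")
  gn <- rownames(sig)
  if (is.null(gn)) gn <- paste0("g", seq_len(nrow(sig)))
  sets <- list(gn)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- gn[pairs[p, 1]]; j <- gn[pairs[p, 2]]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b))
        keep[a] <- FALSE
    }
    sets <- new_sets[keep]
  }
  # order letter sets by their first (highest-ranked) member
  first <- vapply(sets, function(s) min(match(s, gn)), numeric(1))
  sets <- sets[order(first)]
  out <- stats::setNames(rep("", length(gn)), gn)
  for (li in seq_along(sets))
    out[sets[[li]]] <- paste0(out[sets[[li]]], letters[li])
  out
}

#' Protected LSD mean separation with compact letters
#'
#' Fisher's protected least significant difference: pairwise comparisons are
#' attempted only when the omnibus F is significant at `alpha`; otherwise
#' every group shares one letter. When protected, groups i and j differ when
#' \deqn{|m_i - m_j| > t_{1-\alpha/2,\,df_{den}}
#'       \sqrt{MS_W (1/n_i + 1/n_j)}}
#' using the pooled within mean square of the (possibly blocked) ANOVA.
#'
#' @param anova an `anova_fit` carrying group `means` and `ns` (as produced
#'   by [oneway_anova()], [blocked_anova()] or [anova_from_summary()]).
#' @param alpha protection and comparison level.
#' @return object of class `lsd_letters`: `letters` (named, in
#'   descending-mean order), `alpha`, `lsd` (threshold matrix),
#'   `omnibus_significant`, `n_significant_pairs`.
#' @export
protected_lsd <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_fit"))
  m <- anova$means; ns <- anova$ns
  if (is.null(m) || is.null(ns)) stop("anova carries no group means/sizes")
  ord <- order(-m)
  m <- m[ord]; ns <- ns[ord]
  k <- length(m)
  protected_on <- anova$p_value < alpha
  lsd <- matrix(NA_real_, k, k, dimnames = list(names(m), names(m)))
  sig <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  if (protected_on) {
    tcrit <- stats::qt(1 - alpha / 2, anova$df_den)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      lsd[i, j] <- lsd[j, i] <-
        tcrit * sqrt(anova$ms_within * (1 / ns[i] + 1 / ns[j]))
      sig[i, j] <- sig[j, i] <- abs(m[i] - m[j]) > lsd[i, j]
    }
  }
  structure(list(letters = compact_letter_display(sig),
                 means = m, ns = ns, alpha = alpha, lsd = lsd,
                 omnibus_significant = protected_on,
                 n_significant_pairs = sum(sig[upper.tri(sig)])),
            class = "lsd_letters")
}

#' @export
print.lsd_letters <- function(x, ...) {
  cat(sprintf("protected LSD at alpha = %g (omnibus %ssignificant)\n",
              x$alpha, if (x$omnibus_significant) "" else "NOT "))
  print(data.frame(mean = round(x$means, 4), n = as.integer(x$ns),
                   letters = x$letters))
  invisible(x)
}

#' Bonferroni indicator-variable outlier scan
#'
#' For each candidate observation, refits the linear model with a one-hot
#' indicator for that observation added as a covariate; the observation is
#' flagged as an outlier when the indicator's p-value falls below alpha
#' divided by the total number of observations in that fit (Bonferroni
#' correction over all observations, candidate included). The scan is a
#' single pass in candidate order; with `sequential = TRUE` (default) a
#' flagged observation is removed before later candidates are tested.
#'
#' @param records `data.frame` of observations.
#' @param formula model formula for the (already transformed) response, e.g.
#'   `sqrt_count ~ site + week + treatment`.
#' @param candidates integer row indices of the suspicious observations; an
#'   empty vector returns an empty report.
#' @param alpha nominal level before correction.
#' @param sequential remove each flagged observation before testing the next
#'   candidate.
#' @return object of class `outlier_report`: `flagged` row indices,
#'   `p_values` and `thresholds` per candidate, `alpha`, `formula`.
#' @export
bonferroni_outlier_scan <- function(records, formula, candidates,
                                    alpha = 0.05, sequential = TRUE) {
  stopifnot(is.data.frame(records))
  candidates <- as.integer(candidates)
  if (any(candidates < 1L | candidates > nrow(records)))
    stop("candidates must index rows of `records`")
  keep <- rep(TRUE, nrow(records))
  pv <- thr <- stats::setNames(numeric(0), character(0))
  flagged <- integer(0)
  for (cand in candidates) {
    if (!keep[cand]) next
    d <- records[keep, , drop = FALSE]
    d$.ind <- as.integer(seq_len(nrow(records))[keep] == cand)
    f <- stats::update(formula, . ~ . + .ind)
    fit <- stats::lm(f, data = d)
    ct <- summary(fit)$coefficients
    if (!(".ind" %in% rownames(ct)))
      stop("indicator dropped: candidate removal empties a needed cell")
    p <- ct[".ind", "Pr(>|t|)"]
    cut <- alpha / nrow(d)
    pv[as.character(cand)] <- p
    thr[as.character(cand)] <- cut
    if (is.finite(p) && p < cut) {
      flagged <- c(flagged, cand)
      if (sequential) keep[cand] <- FALSE
    }
  }
  structure(list(flagged = flagged, p_values = pv, thresholds = thr,
                 alpha = alpha, formula = formula,
                 n_total = nrow(records)), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Bonferroni outlier scan (alpha = %g / N): %d of %d candidates flagged\n",
              x$alpha, length(x$flagged), length(x$p_values)))
  if (length(x$flagged)) cat("flagged rows:", x$flagged, "\n")
  invisible(x)
}
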