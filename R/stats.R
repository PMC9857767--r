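# Inferential layer: Box-Cox transformation, scanner x distance-group linear
# model with Type-III tests, Tukey-adjusted post hoc contrasts and a compact
# letter display.

bc_apply <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

# Profile log-likelihood of the Box-Cox parameter for a fixed design matrix,
# up to an additive constant: -n/2 log(RSS/n) + (lambda - 1) sum(log y).
bc_profile <- function(y, qrX, lambda_grid) {
  n <- length(y)
  slog <- sum(log(y))
  vapply(lambda_grid, function(l) {
    yl <- bc_apply(y, l)
    rss <- sum(qr.resid(qrX, yl)^2)
    -n / 2 * log(rss / n) + (l - 1) * slog
  }, numeric(1L))
}

#' Box-Cox power transformation
#'
#' y(lambda) = (y^lambda - 1) / lambda for lambda != 0, log(y) at lambda = 0.
#' When `lambda` is not supplied it is estimated by maximizing the profile
#' log-likelihood over a grid from -3 to 3 in steps of 0.01 (intercept-only
#' model; [fit_accuracy_lm()] profiles against the full design instead).
#'
#' Absolute errors can be exactly zero, which the transformation does not
#' admit; `offset` is added first (the model-fitting layer uses +0.5 um).
#'
#' @param values positive values (after `offset`).
#' @param lambda fixed transformation parameter, or `NULL` to estimate.
#' @param offset added to `values` before transforming.
#' @param lambda_grid grid searched when estimating.
#' @return list with `values` (transformed), `lambda`, `offset`.
#' @export
boxcox_transform <- function(values, lambda = NULL, offset = 0,
                             lambda_grid = seq(-3, 3, by = 0.01)) {
  y <- values + offset
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad))
    scanmetry_error(sprintf("non-positive value after offset at record(s): %s",
                            paste(utils::head(bad, 5L), collapse = ", ")),
                    "scanmetry_validation_error")
  if (is.null(lambda)) {
    qrX <- qr(matrix(1, length(y), 1L))
    ll <- bc_profile(y, qrX, lambda_grid)
    lambda <- lambda_grid[which.max(ll)]
  }
  list(values = bc_apply(y, lambda), lambda = lambda, offset = offset)
}

#' Two-factor accuracy linear model with Type-III tests
#'
#' Fits `error ~ scanner + distance_group + scanner:distance_group` on
#' Box-Cox-transformed absolute errors under sum-to-zero contrasts and emits
#' Type-III tests for every term. The degrees of freedom are pure functions of
#' the design: scanner df = S - 1, group df = 1, interaction df = S - 1,
#' residual df = N - 2S for S scanners and two distance groups. Both the
#' F statistic and the corresponding Wald chi-square (F times its numerator
#' df, with a chi-square reference) are reported, so either table style can be
#' reproduced.
#'
#' @param records accuracy-record data.frame holding at least the chosen
#'   metric, with >= 2 scanners, both distance groups and >= 2 records per
#'   scanner x group cell.
#' @param metric `"trueness"` or `"precision"`.
#' @param lambda Box-Cox parameter; `NULL` (default) estimates it by profile
#'   likelihood against the full design matrix.
#' @param offset added to the absolute errors (um) before transforming;
#'   default 0.5 um keeps exact zeros admissible.
#' @param lambda_grid grid for the lambda search.
#' @return Object of class `accuracy_lm`: list with the fitted `model`, the
#'   `anova` table (term, sum_sq, df, F_value, p_value, chisq, p_chisq),
#'   `lambda`, `offset`, `metric` and the model `data`.
#' @export
fit_accuracy_lm <- function(records, metric = c("trueness", "precision"),
                            lambda = NULL, offset = 0.5,
                            lambda_grid = seq(-3, 3, by = 0.01)) {
  metric <- match.arg(metric)
  d <- records[records$metric == metric, , drop = FALSE]
  if (!nrow(d))
    scanmetry_error(sprintf("no %s records", metric), "scanmetry_validation_error")
  d$scanner <- factor(d$scanner_id)
  d$distance_group <- factor(d$group, levels = c("short", "long"))
  if (nlevels(d$scanner) < 2L || nlevels(droplevels(d$distance_group)) < 2L)
    scanmetry_error("need >= 2 scanners and both distance groups",
                    "scanmetry_validation_error")
  cell_n <- table(d$scanner, d$distance_group)
  if (any(cell_n == 0L))
    scanmetry_error("empty scanner x group cell: design is rank deficient (aliased)",
                    "scanmetry_aliasing_error")
  if (any(cell_n < 2L))
    scanmetry_error("need >= 2 replicates per scanner x group cell",
                    "scanmetry_validation_error")

  y <- d$abs_error_um + offset
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad))
    scanmetry_error(sprintf("non-positive error after offset at record(s): %s",
                            paste(utils::head(bad, 5L), collapse = ", ")),
                    "scanmetry_validation_error")
  ctr <- list(scanner = "contr.sum", distance_group = "contr.sum")
  if (is.null(lambda)) {
    X <- stats::model.matrix(~ scanner * distance_group, d, contrasts.arg = ctr)
    ll <- bc_profile(y, qr(X), lambda_grid)
    lambda <- lambda_grid[which.max(ll)]
  }
  d$.response <- bc_apply(y, lambda)
  model <- stats::lm(.response ~ scanner * distance_group, data = d, contrasts = ctr)
  a3 <- car::Anova(model, type = 3)
  tab <- data.frame(term = rownames(a3),
                    sum_sq = a3[["Sum Sq"]],
                    df = as.integer(a3[["Df"]]),
                    F_value = a3[["F value"]],
                    p_value = a3[["Pr(>F)"]])
  tab$chisq <- tab$F_value * tab$df
  tab$p_chisq <- stats::pchisq(tab$chisq, tab$df, lower.tail = FALSE)
  rownames(tab) <- NULL
  structure(list(model = model, anova = tab, lambda = lambda, offset = offset,
                 metric = metric, data = d),
            class = "accuracy_lm")
}

#' @export
print.accuracy_lm <- function(x, ...) {
  cat(sprintf("<accuracy_lm> %s ~ scanner * distance_group (Box-Cox lambda = %g, offset = %g um)\n",
              x$metric, x$lambda, x$offset))
  print(x$anova, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Tukey-adjusted post hoc comparisons with compact letter display
#'
#' All pairwise contrasts of the scanners' estimated marginal means within
#' each distance group, with p-values adjusted by the studentized-range
#' (Tukey) method, plus a compact letter display per group: scanners sharing
#' a letter are not significantly different at `alpha`.
#'
#' @param fit an `accuracy_lm`.
#' @param alpha significance level for the letter display.
#' @return Object of class `tukey_posthoc`: list with `contrasts` (contrast,
#'   group, estimate, SE, df, t_ratio, p_adj), `letters` (group, scanner,
#'   emmean on the transformed scale, letters) and `alpha`.
#' @export
tukey_posthoc <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "accuracy_lm"))
  emm <- emmeans::emmeans(fit$model, ~ scanner | distance_group, data = fit$data)
  prs <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise"),
                               adjust = "tukey"))
  means <- as.data.frame(summary(emm))

  contrasts <- data.frame(contrast = as.character(prs$contrast),
                          group = as.character(prs$distance_group),
                          estimate = prs$estimate,
                          SE = prs$SE,
                          df = prs$df,
                          t_ratio = prs$t.ratio,
                          p_adj = prs$p.value)
  scanners <- levels(fit$data$scanner)
  letter_rows <- lapply(unique(means$distance_group), function(g) {
    sub <- contrasts[contrasts$group == g, ]
    pm <- matrix(NA_real_, length(scanners), length(scanners),
                 dimnames = list(scanners, scanners))
    # emmeans parenthesizes level names that contain characters like "-"
    parts <- lapply(strsplit(sub$contrast, " - ", fixed = TRUE),
                    function(p) gsub("^\\(|\\)$", "", p))
    for (k in seq_along(parts)) {
      a <- parts[[k]][1L]; b <- parts[[k]][2L]
      pm[a, b] <- pm[b, a] <- sub$p_adj[k]
    }
    mu <- means$emmean[means$distance_group == g]
    names(mu) <- as.character(means$scanner[means$distance_group == g])
    mu <- mu[scanners]
    ltr <- compact_letters(pm, mu, alpha = alpha)
    data.frame(group = as.character(g), scanner = scanners,
               emmean = unname(mu), letters = unname(ltr[scanners]))
  })
  structure(list(contrasts = contrasts,
                 letters = do.call(rbind, letter_rows),
                 alpha = alpha),
            class = "tukey_posthoc")
}

#' @export
print.tukey_posthoc <- function(x, ...) {
  cat(sprintf("<tukey_posthoc> alpha = %g\n", x$alpha))
  print(x$letters, row.names = FALSE, digits = 4)
  invisible(x)
}

letter_symbols <- function(k) {
  if (k <= 26L) return(letters[seq_len(k)])
  c(letters, as.vector(outer(letters, letters, paste0)))[seq_len(k)]
}

#' Compact letter display from an adjusted p-value matrix
#'
#' Greedy insert-and-absorb assignment: start with one set holding all groups;
#' for every significantly different pair, split each set containing both;
#' absorb sets contained in another. The result satisfies, for every pair:
#' the two groups share a letter if and only if their adjusted p-value is
#' >= `alpha`. Letters are ordered by ascending group mean (ties broken
#' alphabetically by group name).
#'
#' @param p_matrix symmetric matrix of adjusted p-values with dimnames naming
#'   the groups (diagonal ignored).
#' @param means named numeric vector of group means used to order the letters.
#' @param alpha significance level.
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(p_matrix, means, alpha = 0.05) {
  g <- colnames(p_matrix)
  stopifnot(!is.null(g), setequal(names(means), g))
  sets <- list(g)
  idx <- which(upper.tri(p_matrix), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- g[idx[k, 1L]]; j <- g[idx[k, 2L]]
    p <- p_matrix[idx[k, 1L], idx[k, 2L]]
    if (is.na(p) || p >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb: drop empties, duplicates, and sets strictly contained in another
    new_sets <- new_sets[lengths(new_sets) > 0L]
    key <- vapply(new_sets, function(s) paste(sort(s), collapse = "\r"), character(1L))
    new_sets <- new_sets[!duplicated(key)]
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a != b && keep[b] && length(new_sets[[a]]) < length(new_sets[[b]]) &&
            all(new_sets[[a]] %in% new_sets[[b]])) {
          keep[a] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  # order groups (ascending mean, ties alphabetical), then sets by first member
  ord <- order(means[g], g)
  rank_of <- stats::setNames(seq_along(g), g[ord])
  set_rank <- vapply(sets, function(s) min(rank_of[s]), numeric(1L))
  sets <- sets[order(set_rank)]
  sym <- letter_symbols(length(sets))
  out <- stats::setNames(character(length(g)), g)
  for (k in seq_along(sets)) {
    for (m in sets[[k]]) out[m] <- paste0(out[m], sym[k])
  }
  out
}
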