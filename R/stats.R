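# Group-level statistics for per-animal / per-experiment measurement
# tables: one-sample t test, ordinary two-way ANOVA (Type II sums of
# squares) with Bonferroni post hoc comparisons, and repeated-measures
# two-way ANOVA with the experiment as a complete block.

#' One-sample t test
#'
#' Two-sided test of the sample mean against a null value (e.g. uptake
#' normalized to control, null = 1, or chance preference, null = 50).
#'
#' @param values numeric sample, n >= 2, finite, non-degenerate.
#' @param null_mean null hypothesis mean.
#' @return list of class `t_test_result` with `t`, `df`, `p`, `mean`,
#'   `null_value`.
#' @export
one_sample_t <- function(values, null_mean = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("one_sample_t needs >= 2 finite values")
  }
  if (sd(values) == 0) stop("zero variance: t statistic is undefined")
  tt <- stats::t.test(values, mu = null_mean)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean = mean(values),
                 null_value = null_mean),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("one-sample t test: t(%d) = %.4g, p = %.4g (mean %.4g vs null %.4g)\n",
              x$df, x$t, x$p, x$mean, x$null_value))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`. `m` defaults to the number of p values but
#' can be set to the size of the comparison family actually tested.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param m family size.
#' @return adjusted p values.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), m >= 1)
  pmin(1, pvalues * m)
}

# validate the 2-factor design and return the cell table; errors name
# any empty cell
check_cells <- function(data, factor_a, factor_b) {
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    stop("both factors need at least two levels")
  }
  tab <- table(fa, fb)
  if (any(tab == 0L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s", factor_a,
                 levels(fa)[bad[1L]], factor_b, levels(fb)[bad[2L]]))
  }
  list(fa = fa, fb = fb, tab = tab)
}

# cell-wise Bonferroni post hoc family: comparisons across one factor
# within each level of the other, using the pooled residual mean square
posthoc_cells <- function(data, value, fa, fb, ss_resid, df_resid,
                          alpha = 0.05) {
  mse <- ss_resid / df_resid
  y <- data[[value]]
  comps <- list()
  add_comps <- function(inner, outer, inner_name, outer_name) {
    for (lev in levels(outer)) {
      sel <- outer == lev
      levs <- levels(inner)
      for (i in seq_len(length(levs) - 1L)) {
        for (j in (i + 1L):length(levs)) {
          g1 <- y[sel & inner == levs[i]]
          g2 <- y[sel & inner == levs[j]]
          diff <- mean(g1) - mean(g2)
          se <- sqrt(mse * (1 / length(g1) + 1 / length(g2)))
          tval <- diff / se
          comps[[length(comps) + 1L]] <<- data.frame(
            comparison = sprintf("%s %s vs %s (%s = %s)", inner_name,
                                 levs[i], levs[j], outer_name, lev),
            mean_difference = diff, t = tval,
            p_raw = 2 * pt(-abs(tval), df_resid))
        }
      }
    }
  }
  add_comps(fa, fb, "A", "B")
  add_comps(fb, fa, "B", "A")
  out <- do.call(rbind, comps)
  out$p_adjusted <- bonferroni_adjust(out$p_raw, m = nrow(out))
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

anova_effects_from_car <- function(fit, labels) {
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) {
    # degenerate fits (zero residual SS) break the Type II computation;
    # fall back to the sequential table, which coincides with Type II on
    # the balanced designs where this can happen
    tab1 <- suppressWarnings(stats::anova(fit))
    tab1[, c("Sum Sq", "Df", "F value", "Pr(>F)")]
  })
  tab <- as.data.frame(a2)
  eff <- data.frame(effect = names(labels),
                    ss = tab[labels, "Sum Sq"],
                    df = tab[labels, "Df"],
                    F = tab[labels, "F value"],
                    p = tab[labels, "Pr(>F)"])
  resid_row <- tab["Residuals", ]
  # a perfectly null effect (SS = 0, e.g. identical values) is reported
  # as F = 0, p = 1 rather than 0/0
  zero <- !is.na(eff$ss) & eff$ss < 1e-12
  eff$F[zero] <- 0
  eff$p[zero] <- 1
  if (resid_row$`Sum Sq` < 1e-12) {
    nz <- !zero & !is.na(eff$ss)
    eff$F[nz] <- Inf
    eff$p[nz] <- 0
  }
  list(effects = eff, ss_resid = resid_row$`Sum Sq`,
       df_resid = resid_row$Df)
}

#' Ordinary two-way ANOVA with Bonferroni post hoc comparisons
#'
#' Factorial decomposition of a measurement by two between-subject
#' factors (e.g. age group and genotype) using Type II sums of squares,
#' which coincide with the textbook decomposition on balanced designs
#' and remain well defined for the mildly unbalanced group sizes typical
#' of animal cohorts. Post hoc comparisons are the cell-wise pairs of
#' interest — each factor compared within every level of the other —
#' Bonferroni-adjusted over the family actually tested.
#'
#' @param data data.frame with the value column and both factor columns.
#' @param value name of the measurement column.
#' @param factor_a,factor_b names of the factor columns.
#' @param posthoc logical; compute the Bonferroni post hoc table.
#' @param alpha significance flag level (default 0.05).
#' @return object of class `anova_result`: `effects` (SS, df, F, p for
#'   factor A, factor B, interaction), `ss_resid`, `df_resid`,
#'   `posthoc`.
#' @export
two_way_anova <- function(data, value = "value", factor_a = "age_group",
                          factor_b = "genotype", posthoc = TRUE,
                          alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c(value, factor_a, factor_b) %in% names(data)))
  chk <- check_cells(data, factor_a, factor_b)
  if (all(chk$tab < 2L)) {
    stop("the interaction term needs at least one cell with >= 2 observations")
  }
  df <- data.frame(y = data[[value]], A = chk$fa, B = chk$fb)
  fit <- lm(y ~ A * B, data = df)
  labels <- c(A = "A", B = "B", `A:B` = "A:B")
  names(labels) <- c(factor_a, factor_b,
                     paste0(factor_a, ":", factor_b))
  parts <- anova_effects_from_car(fit, labels)
  ph <- if (posthoc) {
    posthoc_cells(df, "y", df$A, df$B, parts$ss_resid, parts$df_resid,
                  alpha)
  } else NULL
  structure(list(effects = parts$effects, ss_resid = parts$ss_resid,
                 df_resid = parts$df_resid, posthoc = ph,
                 design = "two-way"),
            class = "anova_result")
}

#' Repeated-measures two-way ANOVA (complete blocks)
#'
#' For designs where every block (e.g. one independent culture
#' experiment) is observed in every factor-level combination. The block
#' is entered as an additive factor, removing between-block variance, and
#' the treatment effects are tested against the within-block residual.
#' Incomplete blocks are an error.
#'
#' @param data data.frame with value, two factor columns, and a block
#'   column.
#' @param value,factor_a,factor_b as in [two_way_anova()].
#' @param block name of the block (experiment) column.
#' @param posthoc,alpha as in [two_way_anova()].
#' @return an `anova_result` (with a `block` row in `effects`).
#' @export
repeated_measures_two_way_anova <- function(data, value = "value",
                                            factor_a = "treatment",
                                            factor_b = "condition",
                                            block = "experiment",
                                            posthoc = TRUE,
                                            alpha = 0.05) {
  stopifnot(is.data.frame(data),
            all(c(value, factor_a, factor_b, block) %in% names(data)))
  chk <- check_cells(data, factor_a, factor_b)
  blk <- factor(data[[block]])
  cell <- interaction(chk$fa, chk$fb, drop = TRUE)
  complete <- table(blk, cell)
  if (any(complete == 0L)) {
    stop("incomplete blocks: every block must be observed in every condition")
  }
  df <- data.frame(y = data[[value]], A = chk$fa, B = chk$fb,
                   block = blk)
  fit <- lm(y ~ block + A * B, data = df)
  labels <- c(block = "block", A = "A", B = "B", `A:B` = "A:B")
  names(labels) <- c(block, factor_a, factor_b,
                     paste0(factor_a, ":", factor_b))
  parts <- anova_effects_from_car(fit, labels)
  ph <- if (posthoc) {
    posthoc_cells(df, "y", df$A, df$B, parts$ss_resid, parts$df_resid,
                  alpha)
  } else NULL
  structure(list(effects = parts$effects, ss_resid = parts$ss_resid,
                 df_resid = parts$df_resid, posthoc = ph,
                 design = "repeated-measures two-way"),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s ANOVA (Type II SS)\n", x$design))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-24s SS = %-10.5g F(%d, %d) = %-8.4g p = %.4g\n",
                eff$effect[i], eff$ss[i], eff$df[i], x$df_resid,
                eff$F[i], eff$p[i]))
  }
  cat(sprintf("  residual: SS = %.5g on %d df\n", x$ss_resid, x$df_resid))
  if (!is.null(x$posthoc)) {
    cat(sprintf("  post hoc (Bonferroni, m = %d): %d of %d significant\n",
                nrow(x$posthoc), sum(x$posthoc$significant),
                nrow(x$posthoc)))
  }
  invisible(x)
}
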