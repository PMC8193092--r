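# Significance machinery for context comparisons: one-way ANOVA across
# groups, Tukey HSD pairwise comparisons when the ANOVA rejects, and a
# deterministic compact letter display (groups sharing a letter do not
# differ at level alpha).

#' Compare community contexts with ANOVA, Tukey HSD and letters
#'
#' Replicate-level estimates (e.g. per-replicate fitted parameters) grouped
#' by context are compared by one-way ANOVA; if the ANOVA p-value is below
#' `alpha`, Tukey HSD supplies pairwise p-values and a compact letter
#' display is built (otherwise all groups share the letter "a"). Letters
#' are assigned deterministically in order of descending group mean.
#' Groups with fewer than 2 values are excluded with a warning. Welch's
#' ANOVA ([stats::oneway.test()]) is available for heteroscedastic groups;
#' pairwise letters then come from pairwise Welch t-tests with Holm
#' adjustment.
#'
#' @param estimates Data frame with columns `context` and `value`, or a
#'   named list of numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @param welch Use Welch's ANOVA / pairwise Welch t-tests instead of
#'   classical ANOVA + Tukey HSD.
#' @return A list of class `letter_display`: `letters` (tibble `context`,
#'   `mean`, `n`, `letter`, ordered by descending mean), `anova_p`,
#'   `pairwise` (tibble `context_a`, `context_b`, `p_value`; empty when the
#'   ANOVA does not reject), `alpha`, `method`.
#' @export
compare_contexts <- function(estimates, alpha = 0.05, welch = FALSE) {
  df <- as_estimate_table(estimates)
  counts <- table(df$context)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("excluding context(s) with < 2 estimates: ",
            paste(small, collapse = ", "), call. = FALSE)
    df <- df[!df$context %in% small, , drop = FALSE]
  }
  contexts <- unique(df$context)
  if (length(contexts) < 2) {
    stop("need >= 2 contexts with >= 2 estimates each", call. = FALSE)
  }
  df$context <- factor(df$context)
  means <- vapply(split(df$value, df$context), mean, numeric(1))
  ord <- names(sort(means, decreasing = TRUE))

  if (welch) {
    anova_p <- stats::oneway.test(value ~ context, data = df,
                                  var.equal = FALSE)$p.value
  } else {
    fit <- stats::aov(value ~ context, data = df)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }

  if (is.finite(anova_p) && anova_p < alpha) {
    pw <- if (welch) pairwise_welch(df) else pairwise_tukey(df)
  } else {
    pw <- tibble::tibble(context_a = character(), context_b = character(),
                         p_value = numeric())
  }
  letters <- letter_display(ord, pw, alpha)
  structure(list(
    letters = tibble::tibble(
      context = ord,
      mean = unname(means[ord]),
      n = as.integer(counts[ord]),
      letter = letters
    ),
    anova_p = anova_p,
    pairwise = pw,
    alpha = alpha,
    method = if (welch) "welch" else "anova-tukey"
  ), class = "letter_display")
}

as_estimate_table <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, is.numeric, logical(1)))) {
    estimates <- tibble::tibble(
      context = rep(names(estimates), lengths(estimates)),
      value = unlist(estimates, use.names = FALSE)
    )
  }
  stopifnot(is.data.frame(estimates),
            all(c("context", "value") %in% names(estimates)))
  out <- estimates[is.finite(estimates$value), c("context", "value")]
  out$context <- as.character(out$context)
  out
}

pairwise_tukey <- function(df) {
  fit <- stats::aov(value ~ context, data = df)
  tk <- stats::TukeyHSD(fit)$context
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(
    context_a = vapply(pairs, `[`, "", 1),
    context_b = vapply(pairs, `[`, "", 2),
    p_value = unname(tk[, "p adj"])
  )
}

pairwise_welch <- function(df) {
  cmb <- utils::combn(levels(df$context), 2)
  p <- apply(cmb, 2, function(pair) {
    stats::t.test(df$value[df$context == pair[1]],
                  df$value[df$context == pair[2]])$p.value
  })
  tibble::tibble(context_a = cmb[1, ], context_b = cmb[2, ],
                 p_value = stats::p.adjust(p, method = "holm"))
}

# Insert-absorb compact letter display. `ord` lists groups by descending
# mean; `pairwise` holds adjusted p-values; pairs with p < alpha must not
# share a letter.
letter_display <- function(ord, pairwise, alpha) {
  sets <- list(ord)
  sig <- pairwise[pairwise$p_value < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$context_a[i]
    b <- sig$context_b[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another; drop empties; deduplicate
    new_sets <- Filter(length, new_sets)
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) {
      for (k in seq_along(new_sets)) {
        if (j != k && keep[j] &&
            all(new_sets[[j]] %in% new_sets[[k]]) &&
            (length(new_sets[[j]]) < length(new_sets[[k]]) || j > k)) {
          keep[j] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  # order letter sets by the position of their highest-mean member
  first_pos <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(first_pos)]
  unname(vapply(ord, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1)))
}

#' @export
print.letter_display <- function(x, ...) {
  cat(sprintf("<letter_display> %s, ANOVA p = %.4g, alpha = %g\n",
              x$method, x$anova_p, x$alpha))
  print(x$letters)
  invisible(x)
}

#' Diversity-level effect on nitrogen fixation
#'
#' Tests whether \%Ndfa differs among diversity levels (mixture,
#' monoculture, isolated single), treating weekly means as replicate
#' observations — the convention when fixation shows no trend across
#' harvest weeks. ANOVA across levels with Tukey HSD post hoc; the report
#' names levels significantly lower than the highest-mean level.
#'
#' @param ndfa_records Tibble with columns `diversity` and `ndfa` (e.g.
#'   from [ndfa_timeseries()] or [field_ndfa()]).
#' @param alpha Significance level.
#' @param welch Use Welch's ANOVA instead.
#' @return A list of class `diversity_effect`: the `letter_display`, plus
#'   `lower_levels` (levels with a letter set disjoint from the top
#'   level's) and `significant` (ANOVA rejection).
#' @export
diversity_effect_ndfa <- function(ndfa_records, alpha = 0.05,
                                  welch = FALSE) {
  stopifnot(all(c("diversity", "ndfa") %in% names(ndfa_records)))
  cmp <- compare_contexts(
    tibble::tibble(context = ndfa_records$diversity,
                   value = ndfa_records$ndfa),
    alpha = alpha, welch = welch
  )
  top <- strsplit(cmp$letters$letter[1], "")[[1]]
  lower <- cmp$letters$context[
    vapply(strsplit(cmp$letters$letter, ""),
           function(l) length(intersect(l, top)) == 0, logical(1))
  ]
  structure(list(
    display = cmp,
    significant = is.finite(cmp$anova_p) && cmp$anova_p < alpha,
    lower_levels = lower
  ), class = "diversity_effect")
}

#' @export
print.diversity_effect <- function(x, ...) {
  cat(sprintf("<diversity_effect> %s (ANOVA p = %.4g)\n",
              if (x$significant) "significant" else "not significant",
              x$display$anova_p))
  if (length(x$lower_levels) > 0) {
    cat("  lower than the top level:",
        paste(x$lower_levels, collapse = ", "), "\n")
  }
  print(x$display$letters)
  invisible(x)
}
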