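# qPCR relative quantification (Livak 2^-ddCt), one-way ANOVA and
# Duncan's multiple range test with compact letter display.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged first; per biological replicate,
#' `dCT = Ct_target - Ct_reference`; `ddCT` subtracts the mean dCT of
#' the calibrator treatment, and the reported value is `2^-ddCT`.  The
#' calibrator-treatment mean of ddCT is zero by construction.
#'
#' @param ct_table data.frame with columns `gene`, `treatment`,
#'   `bio_rep`, `tech_rep`, `ct`; the reference gene appears as ordinary
#'   rows under its own gene name.
#' @param reference_gene name of the internal-standard gene (e.g.
#'   `"18sRNA"`).
#' @param calibrator treatment used as calibrator (e.g. `"CK"`).
#' @return list with `per_rep` (gene, treatment, bio_rep, rel_expr) and
#'   `summary` (gene, treatment, mean, sd over biological replicates).
#' @export
relative_expression_ddct <- function(ct_table, reference_gene,
                                     calibrator) {
  need <- c("gene", "treatment", "bio_rep", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(ct_table$ct))) {
    stop("non-finite Ct values", call. = FALSE)
  }
  # average technical replicates
  agg <- stats::aggregate(ct ~ gene + treatment + bio_rep,
                          data = ct_table, FUN = mean)
  ref <- agg[agg$gene == reference_gene, , drop = FALSE]
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  if (!nrow(ref)) {
    stop("reference gene '", reference_gene, "' absent from table",
         call. = FALSE)
  }
  key <- function(d) paste(d$treatment, d$bio_rep)
  ref_ct <- stats::setNames(ref$ct, key(ref))
  miss <- !key(tgt) %in% names(ref_ct)
  if (any(miss)) {
    stop("missing reference rows for sample(s): ",
         paste(unique(key(tgt)[miss]), collapse = ", "), call. = FALSE)
  }
  tgt$dct <- tgt$ct - ref_ct[key(tgt)]
  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(d) {
    cal <- d$dct[d$treatment == calibrator]
    if (!length(cal)) {
      stop("gene ", d$gene[1], " has no calibrator ('", calibrator,
           "') samples", call. = FALSE)
    }
    d$ddct <- d$dct - mean(cal)
    d$rel_expr <- 2^(-d$ddct)
    d
  }))
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(split(out, list(out$gene, out$treatment),
                                      drop = TRUE), function(d) {
    data.frame(gene = d$gene[1], treatment = d$treatment[1],
               mean = mean(d$rel_expr), sd = stats::sd(d$rel_expr),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_rep = out[, c("gene", "treatment", "bio_rep", "rel_expr")],
       summary = summ)
}

#' One-way ANOVA
#'
#' Standard between/within decomposition with the p-value from the F
#' distribution.  Zero within-group variance with unequal means is
#' reported as `F = Inf`, `p = 0`.
#'
#' @param groups named list of numeric replicate vectors (one per
#'   treatment), each of length >= 2.
#' @return list: `f`, `df_between`, `df_within`, `p`, `mse`, `ss_between`,
#'   `ss_within`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  ssb <- sum(lengths(groups) *
               (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(all_x) - length(groups)
  mse <- ssw / dfw
  if (mse == 0) {
    f <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    f <- (ssb / dfb) / mse
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  list(f = f, df_between = dfb, df_within = dfw, p = p, mse = mse,
       ss_between = ssb, ss_within = ssw)
}

# critical range for a comparison spanning p ordered means
duncan_range <- function(p, df, mse, n_h, alpha) {
  level <- (1 - alpha)^(p - 1)
  stats::qtukey(level, nmeans = p, df = df) * sqrt(mse / n_h)
}

#' Duncan's multiple range test with compact letter display
#'
#' Means are sorted descending; a comparison spanning `p` ordered means
#' uses the critical range
#' `R_p = q(1 - (1-alpha)^(p-1); p, df) * sqrt(MSE / n_h)` with `q` the
#' studentized-range quantile and `n_h` the harmonic mean group size.
#' Two means differ iff their gap exceeds `R_p` and no enclosing
#' non-significant span covers both.  Letters are assigned to the
#' maximal non-significant spans; the highest mean gets `a`.
#'
#' @param means named numeric vector of group means.
#' @param n group sizes (scalar or vector aligned with `means`).
#' @param mse mean square error from the ANOVA.
#' @param df residual degrees of freedom.
#' @param alpha protection level (default 0.05).
#' @return list with `letters` (named by treatment, sorted by descending
#'   mean) and `nonsig` (logical matrix of pairwise non-difference).
#' @export
duncan_letters <- function(means, n, mse, df, alpha = 0.05) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (mse < 0) stop("MSE must be >= 0", call. = FALSE)
  k <- length(means)
  if (length(n) == 1) n <- rep(n, k)
  if (length(unique(n)) > 1) {
    warning("unequal group sizes: using harmonic mean")
  }
  n_h <- k / sum(1 / n)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]

  # nonsig[i, j]: means i..j (in sorted order) do not differ, either
  # directly (gap <= R_p) or because an enclosing span is non-significant.
  nonsig <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  diag(nonsig) <- TRUE
  protected <- matrix(FALSE, k, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (protected[i, j]) {
        nonsig[i, j] <- nonsig[j, i] <- TRUE
        next
      }
      rp <- duncan_range(span, df, mse, n_h, alpha)
      if ((m[i] - m[j]) <= rp) {
        nonsig[i, j] <- nonsig[j, i] <- TRUE
        # protect all enclosed spans
        for (a in i:j) for (b in a:j) protected[a, b] <- TRUE
      }
    }
  }

  letters_out <- cld_from_spans(nonsig)
  names(letters_out) <- names(m)
  list(letters = letters_out, nonsig = nonsig, order = names(m))
}

# compact letter display from a contiguous non-significance structure:
# maximal spans [i, j] with nonsig[i, j] each receive one letter.
cld_from_spans <- function(nonsig) {
  k <- nrow(nonsig)
  spans <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    spans[[i]] <- c(i, j)
  }
  # keep maximal spans only
  keep <- vapply(seq_along(spans), function(s) {
    !any(vapply(seq_along(spans), function(t) {
      t != s && spans[[t]][1] <= spans[[s]][1] &&
        spans[[t]][2] >= spans[[s]][2]
    }, logical(1)))
  }, logical(1))
  spans <- unique(spans[keep])
  spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
  out <- rep("", k)
  for (s in seq_along(spans)) {
    rng <- spans[[s]][1]:spans[[s]][2]
    out[rng] <- paste0(out[rng], letters[s])
  }
  out
}

#' Per-gene qPCR analysis: ddCt + ANOVA + Duncan letters
#'
#' @inheritParams relative_expression_ddct
#' @inheritParams duncan_letters
#' @return data.frame with one row per (gene, treatment): mean, sd,
#'   ANOVA F and p (replicated per gene), Duncan letter.
#' @export
qpcr_analysis <- function(ct_table, reference_gene, calibrator,
                          alpha = 0.05) {
  rel <- relative_expression_ddct(ct_table, reference_gene, calibrator)
  out <- lapply(split(rel$per_rep, rel$per_rep$gene), function(d) {
    groups <- split(d$rel_expr, d$treatment)
    av <- anova_oneway(groups)
    means <- vapply(groups, mean, numeric(1))
    dl <- duncan_letters(means, n = lengths(groups), mse = av$mse,
                         df = av$df_within, alpha = alpha)
    data.frame(gene = d$gene[1], treatment = dl$order,
               mean = means[dl$order],
               sd = vapply(groups[dl$order], stats::sd, numeric(1)),
               f = av$f, p = av$p, letter = dl$letters[dl$order],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
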