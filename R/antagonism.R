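#' Partition genes by which contrasts call them
#'
#' Joins the three classified contrasts (heterozygous-mother vs WT,
#' heterozygous-father vs WT, null vs WT) on their shared gene universe and
#' labels each gene by which contrasts call it misregulated, recording the
#' direction separately per contrast.
#'
#' @param res_mat,res_pat,res_null classified results
#'   (see [classify_differential()]) for the three contrasts.
#' @return Data frame: `gene_id`, per-contrast `log2fc_*` and `call_*`,
#'   and `set_label` in `mat_only`, `pat_only`, `null_only`, `both_het`,
#'   `mat_and_null`, `pat_and_null`, `none`.
#' @export
partition_sets <- function(res_mat, res_pat, res_null) {
  ids <- Reduce(intersect, list(res_mat$feature_id, res_pat$feature_id,
                                res_null$feature_id))
  if (length(ids) < length(res_mat$feature_id) ||
      length(ids) < length(res_pat$feature_id) ||
      length(ids) < length(res_null$feature_id))
    warnf("gene universes differ; restricting to %d shared genes",
          length(ids))
  pick <- function(res) res[match(ids, res$feature_id), ]
  m <- pick(res_mat); p <- pick(res_pat); n <- pick(res_null)
  called <- function(res) res$call %in% c("up", "down")
  cm <- called(m); cp <- called(p); cn <- called(n)
  lab <- rep("none", length(ids))
  lab[cm] <- "mat_only"
  lab[cp] <- "pat_only"
  lab[cn] <- "null_only"
  lab[cm & cn & !cp] <- "mat_and_null"
  lab[cp & cn & !cm] <- "pat_and_null"
  lab[cm & cp] <- "both_het"
  data.frame(gene_id = ids,
             log2fc_mat = m$log2_fold_change, call_mat = m$call,
             log2fc_pat = p$log2_fold_change, call_pat = p$call,
             log2fc_null = n$log2_fold_change, call_null = n$call,
             set_label = lab)
}

#' Test for opposite-direction misregulation in the reciprocal heterozygotes
#'
#' Genes called misregulated in both heterozygote contrasts are "shared";
#' a shared gene whose estimated fold changes have opposite signs changed
#' in the opposite direction. Enrichment of opposite-direction genes is
#' evaluated exactly against the shared-set composition: given the marginal
#' numbers of up-calls in each contrast, the count of concordant up/up genes
#' is hypergeometric under independence, and an excess of opposite pairs is
#' its lower tail.
#'
#' @param res_mat,res_pat classified results for the two heterozygote
#'   contrasts on a shared universe.
#' @return List: `n_shared`, `n_opposite`, `p_value` (`NA` when no genes
#'   are shared), and the shared genes' table.
#' @export
opposite_direction_test <- function(res_mat, res_pat) {
  ids <- intersect(res_mat$feature_id, res_pat$feature_id)
  m <- res_mat[match(ids, res_mat$feature_id), ]
  p <- res_pat[match(ids, res_pat$feature_id), ]
  shared <- m$call %in% c("up", "down") & p$call %in% c("up", "down")
  n_shared <- sum(shared)
  if (n_shared == 0)
    return(list(n_shared = 0L, n_opposite = 0L, p_value = NA_real_,
                genes = data.frame()))
  sm <- sign(m$log2_fold_change[shared])
  sp <- sign(p$log2_fold_change[shared])
  opp <- sm != sp
  n_mat_up <- sum(sm > 0)
  n_pat_up <- sum(sp > 0)
  x_concordant_up <- sum(sm > 0 & sp > 0)
  p_val <- stats::phyper(x_concordant_up, n_mat_up, n_shared - n_mat_up,
                         n_pat_up)
  list(n_shared = as.integer(n_shared), n_opposite = as.integer(sum(opp)),
       p_value = p_val,
       genes = data.frame(gene_id = ids[shared],
                          log2fc_mat = m$log2_fold_change[shared],
                          log2fc_pat = p$log2_fold_change[shared],
                          opposite = opp))
}

#' Predict the double-mutant effect from additive parental effects
#'
#' If loss of Pol IV has no zygotic effect on a gene, the change observed
#' in the null is the sum of the two parental effects on the log scale:
#' predicted log2FC(null) = log2FC(mat het) + log2FC(pat het). Genes
#' missing either heterozygote estimate are skipped.
#'
#' @param res_mat,res_pat classified (or raw [nb_test()]) results for the
#'   heterozygote contrasts.
#' @param res_null optional null-contrast results; when given, the observed
#'   minus predicted discrepancy is reported per gene.
#' @return Data frame: `gene_id`, `predicted_log2fc`, `predicted_fold`,
#'   and, when available, `observed_log2fc` and `discrepancy`.
#' @export
additive_prediction <- function(res_mat, res_pat, res_null = NULL) {
  ids <- intersect(res_mat$feature_id, res_pat$feature_id)
  lm_ <- res_mat$log2_fold_change[match(ids, res_mat$feature_id)]
  lp <- res_pat$log2_fold_change[match(ids, res_pat$feature_id)]
  keep <- !is.na(lm_) & !is.na(lp)
  out <- data.frame(gene_id = ids[keep],
                    predicted_log2fc = lm_[keep] + lp[keep])
  out$predicted_fold <- 2^out$predicted_log2fc
  if (!is.null(res_null)) {
    obs <- res_null$log2_fold_change[match(out$gene_id,
                                           res_null$feature_id)]
    out$observed_log2fc <- obs
    out$discrepancy <- obs - out$predicted_log2fc
  }
  out
}

#' Least-squares slope of the paternal on the maternal effect
#'
#' Ordinary least squares of `y` on `x` over a gene set, reporting slope,
#' intercept and R squared; the inverse maternal/paternal relationship
#' shows up as a negative slope.
#'
#' @param x,y numeric vectors (log2 fold changes in the two contrasts).
#' @return List: `slope`, `intercept`, `r_squared`, `n`; all `NA` with
#'   fewer than 3 complete pairs or zero variance in `x`.
#' @export
inverse_slope <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3 || stats::var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n = length(x)))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = length(x))
}
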