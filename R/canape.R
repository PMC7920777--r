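#' Categorical analysis of neo- and paleo-endemism (CANAPE)
#'
#' Two-step classification of grid cells from the randomization quantiles of
#' phylogenetic endemism. Step 1 (candidacy): a cell is an endemism hotspot
#' if PE on the original tree or PE on the equal-branch-length comparison
#' tree is significantly high (one-tailed, `q >= 1 - alpha_one_tail`); all
#' other cells are `not_significant`. Step 2 (character): among candidates,
#' a significantly high RPE quantile marks *paleo*-endemism (an excess of
#' range-restricted long branches — old lineages), a significantly low one
#' marks *neo*-endemism (range-restricted short branches — recent
#' radiations), and the remainder are *mixed*. Mixed cells whose two PE
#' quantiles are both extreme at `alpha_super` are labelled *super*
#' (optionally collapsed back into mixed).
#'
#' @param sig A `ps_significance` object containing the `PE_orig`, `PE_alt`
#'   and `RPE` metrics, or a data frame with columns `cell_id`, `q_PE_orig`,
#'   `q_PE_alt`, `q_RPE`.
#' @param alpha_one_tail One-tailed candidacy level (default 0.05).
#' @param alpha_rpe_tail Per-tail level for the RPE split (default 0.025).
#' @param alpha_super Level for the super-endemic subcategory (default 0.01).
#' @param collapse_super If `TRUE`, report super cells as mixed (3-way
#'   scheme).
#' @return A data frame of class `ps_canape` with columns `cell_id`,
#'   `q_PE_orig`, `q_PE_alt`, `q_RPE`, `category` (factor with levels
#'   `not_significant`, `neo`, `paleo`, `mixed`, `super`).
#' @export
classify_canape <- function(sig, alpha_one_tail = 0.05, alpha_rpe_tail = 0.025,
                            alpha_super = 0.01, collapse_super = FALSE) {
  if (inherits(sig, "ps_significance")) {
    qm <- attr(sig, "q_matrix")
    need <- c("PE_orig", "PE_alt", "RPE")
    if (!all(need %in% colnames(qm))) {
      stop("significance object lacks metrics: ",
           paste(setdiff(need, colnames(qm)), collapse = ", "))
    }
    df <- data.frame(cell_id = rownames(qm),
                     q_PE_orig = qm[, "PE_orig"],
                     q_PE_alt = qm[, "PE_alt"],
                     q_RPE = qm[, "RPE"],
                     stringsAsFactors = FALSE, row.names = NULL)
  } else {
    stopifnot(is.data.frame(sig),
              all(c("cell_id", "q_PE_orig", "q_PE_alt", "q_RPE") %in% names(sig)))
    df <- sig[, c("cell_id", "q_PE_orig", "q_PE_alt", "q_RPE")]
  }
  candidate <- df$q_PE_orig >= 1 - alpha_one_tail | df$q_PE_alt >= 1 - alpha_one_tail
  if (anyNA(candidate) || (any(candidate) && anyNA(df$q_RPE[candidate]))) {
    stop("missing quantile for a candidate cell")
  }
  cat_out <- rep("not_significant", nrow(df))
  cat_out[candidate & df$q_RPE >= 1 - alpha_rpe_tail] <- "paleo"
  cat_out[candidate & df$q_RPE <= alpha_rpe_tail] <- "neo"
  mixed <- candidate & df$q_RPE > alpha_rpe_tail & df$q_RPE < 1 - alpha_rpe_tail
  cat_out[mixed] <- "mixed"
  super <- mixed & df$q_PE_orig >= 1 - alpha_super & df$q_PE_alt >= 1 - alpha_super
  if (!collapse_super) cat_out[super] <- "super"
  df$category <- factor(cat_out,
                        levels = c("not_significant", "neo", "paleo", "mixed", "super"))
  class(df) <- c("ps_canape", "data.frame")
  df
}

#' @export
print.ps_canape <- function(x, ...) {
  cat("<ps_canape> ", nrow(x), " cells\n", sep = "")
  print(table(x$category))
  invisible(x)
}
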