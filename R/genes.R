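#' Benjamini–Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (a thin,
#' input-validated wrapper over `stats::p.adjust(method = "BH")`, kept as
#' the module's named surface).
#'
#' @param p_values finite p-values in \[0, 1\].
#' @return Adjusted q-values, elementwise >= the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Read a staged differential-expression table
#'
#' Expects a TSV with columns `gene`, `lfc_mid_vs_early`, `lfc_end_vs_mid`
#' and either per-transition q-value columns (`q_mid_vs_early`,
#' `q_end_vs_mid`) or p-value columns from which q-values can be derived.
#'
#' @param path file path; defaults to the packaged table of 42
#'   progressively upregulated genes from a staged mouse glioma model
#'   (average log2 fold changes for the mid-vs-early and end-vs-mid
#'   transitions; the published table prints no p-values, so the packaged
#'   q columns are 0.01 placeholders that isolate the fold-change logic).
#' @return Tibble.
#' @export
read_de_table <- function(path = progression_genes_path()) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Path of the packaged progression-gene table
#' @return File path under the installed package.
#' @export
progression_genes_path <- function() {
  system.file("extdata", "progression_genes_log2fc.tsv",
              package = "gliomaconn", mustWork = TRUE)
}

ensure_q_columns <- function(table) {
  for (tr in c("mid_vs_early", "end_vs_mid")) {
    qc <- paste0("q_", tr)
    if (!qc %in% names(table)) {
      pc <- paste0("p_", tr)
      if (!pc %in% names(table)) {
        stop("table needs either ", qc, " or ", pc)
      }
      table[[qc]] <- bh_adjust(table[[pc]])
    }
  }
  table
}

#' Sequentially upregulated genes across two progression transitions
#'
#' Selects genes whose expression rises through both stage transitions
#' (early -> mid and mid -> end): log2 fold change >= `lfc_min` AND
#' adjusted q < `q_max` in both transitions. The selection demands
#' positive fold changes (progressive upregulation); `signed = FALSE`
#' switches to the absolute-value reading of the threshold.
#'
#' @param table DE tibble (see [read_de_table()]); q columns are derived
#'   from p columns via [bh_adjust()] when absent.
#' @param lfc_min log2 fold-change threshold (default 0.25).
#' @param q_max adjusted-p threshold (default 0.05).
#' @param signed require positive fold changes (default TRUE).
#' @return Tibble of selected rows, original order preserved.
#' @export
sequential_upregulated <- function(table, lfc_min = 0.25, q_max = 0.05,
                                   signed = TRUE) {
  need <- c("gene", "lfc_mid_vs_early", "lfc_end_vs_mid")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(table) == 0) return(tibble::as_tibble(table))
  if (anyDuplicated(table$gene)) stop("gene ids must be unique")
  table <- ensure_q_columns(table)
  lfc1 <- table$lfc_mid_vs_early
  lfc2 <- table$lfc_end_vs_mid
  if (!signed) {
    lfc1 <- abs(lfc1); lfc2 <- abs(lfc2)
  }
  keep <- lfc1 >= lfc_min & lfc2 >= lfc_min &
    table$q_mid_vs_early < q_max & table$q_end_vs_mid < q_max
  tibble::as_tibble(table[keep, , drop = FALSE])
}

#' Gene with the largest fold change in one transition
#'
#' @param table DE tibble.
#' @param which_transition `"end_vs_mid"` or `"mid_vs_early"`.
#' @return List with `gene` and `value`; ties broken by lexicographic
#'   gene id.
#' @export
max_transition_lfc <- function(table,
                               which_transition = c("end_vs_mid",
                                                    "mid_vs_early")) {
  which_transition <- match.arg(which_transition)
  if (nrow(table) == 0) stop("empty table")
  col <- paste0("lfc_", which_transition)
  stopifnot(col %in% names(table))
  ord <- order(-table[[col]], table$gene)
  list(gene = table$gene[ord[1]], value = table[[col]][ord[1]])
}

#' Synthetic null DE table
#'
#' Gaussian log2 fold changes (mean 0) and uniform p-values in both
#' transitions — a null instrument for specificity checks of the
#' sequential filter.
#'
#' @param n_genes number of rows.
#' @param seed RNG seed.
#' @param lfc_sd SD of the null fold changes (default 0.1).
#' @return Tibble with gene/lfc/p/q columns.
#' @export
simulate_de_table <- function(n_genes = 1000L, seed = 1L, lfc_sd = 0.1) {
  set.seed(seed)
  tab <- tibble::tibble(
    gene = sprintf("gene%05d", seq_len(n_genes)),
    lfc_mid_vs_early = rnorm(n_genes, 0, lfc_sd),
    lfc_end_vs_mid = rnorm(n_genes, 0, lfc_sd),
    p_mid_vs_early = runif(n_genes),
    p_end_vs_mid = runif(n_genes))
  tab$q_mid_vs_early <- bh_adjust(tab$p_mid_vs_early)
  tab$q_end_vs_mid <- bh_adjust(tab$p_end_vs_mid)
  tab
}
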