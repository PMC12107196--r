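#' Per-code admission-risk profiles
#'
#' One profile per distinct primary ICD-10 code: presentation count,
#' admission count and the admission risk as their exact fraction.
#'
#' @param records registry data frame (filtered and categorized).
#' @return data frame with columns `code`, `n`, `n_admitted`, `risk`, sorted
#'   by code; zero rows for empty input.
#' @export
compute_code_risks <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(code = character(), n = integer(),
                      n_admitted = integer(), risk = numeric(),
                      stringsAsFactors = FALSE))
  }
  n <- table(records$icd10)
  adm <- tapply(records$admitted, records$icd10, sum)
  codes <- sort(names(n))
  data.frame(code = codes,
             n = as.integer(n[codes]),
             n_admitted = as.integer(adm[codes]),
             risk = as.numeric(adm[codes] / n[codes]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-block admission-risk profiles
#'
#' Pools presentations over WHO ICD-10 blocks (block n and admissions are the
#' sums over member codes) for block-level clustering.
#'
#' @param records registry data frame.
#' @param blocks a block table from [parse_block_table()] / [icd10_blocks()].
#' @return data frame with columns `code` (the block id), `n`, `n_admitted`,
#'   `risk`.
#' @export
compute_block_risks <- function(records, blocks = icd10_blocks()) {
  block <- code_to_block(records$icd10, blocks)
  if (anyNA(block)) {
    offending <- sort(unique(records$icd10[is.na(block)]))
    abort(paste0("codes not covered by the block table: ",
                 paste(offending, collapse = ", ")), "edrisk_domain_error")
  }
  rec <- records
  rec$icd10 <- block
  compute_code_risks(rec)
}

#' Attach cluster labels to presentations
#'
#' Each presentation inherits the cluster of its primary diagnosis code from
#' a fitted [kmeans_1d()] / [kmeans_1d_exact()] model whose assignment vector
#' is named by code (as produced when clustering `risk` values named by
#' `code`).
#'
#' @param records registry data frame.
#' @param model a `cluster_model` with a named `cluster` vector.
#' @return the records with an integer `cluster` column.
#' @export
propagate_clusters <- function(records, model) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(names(model$cluster))) {
    abort("cluster model assignment is unnamed; cluster named risk values",
          "edrisk_domain_error")
  }
  idx <- match(records$icd10, names(model$cluster))
  if (anyNA(idx)) {
    offending <- sort(unique(records$icd10[is.na(idx)]))
    abort(paste0("codes without a cluster assignment: ",
                 paste(offending, collapse = ", ")), "edrisk_domain_error")
  }
  records$cluster <- unname(model$cluster[idx])
  records
}
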