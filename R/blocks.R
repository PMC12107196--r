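#' Parse an ICD-10 block-definition table
#'
#' Reads a delimited table with columns `block_id` (a range of 3-character
#' prefixes such as `"J09-J18"`), `title` and `chapter`, validates the range
#' strings, checks that ranges do not overlap, and returns the definitions
#' sorted by range start.
#'
#' @param path path to a comma-delimited file.
#' @return data frame of class `block_table` with columns `block_id`,
#'   `title`, `chapter`, `start`, `end`.
#' @export
parse_block_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block_id", "title", "chapter")
  if (!all(need %in% names(raw))) {
    abort("block table needs columns block_id, title, chapter",
          "edrisk_parse_error")
  }
  if (nrow(raw) == 0) {
    out <- raw[need]
    out$start <- character(); out$end <- character()
    class(out) <- c("block_table", "data.frame")
    return(out)
  }
  bad <- which(!grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", raw$block_id))
  if (length(bad)) {
    abort(sprintf("malformed block range '%s' at line %d", raw$block_id[bad[1]],
                  bad[1] + 1L), "edrisk_parse_error")
  }
  start <- sub("-.*", "", raw$block_id)
  end <- sub(".*-", "", raw$block_id)
  bad <- which(prefix_key(start) > prefix_key(end))
  if (length(bad)) {
    abort(sprintf("block range start exceeds end ('%s') at line %d",
                  raw$block_id[bad[1]], bad[1] + 1L), "edrisk_parse_error")
  }
  ord <- order(prefix_key(start))
  out <- raw[ord, need, drop = FALSE]
  out$start <- start[ord]
  out$end <- end[ord]
  overlap <- which(prefix_key(out$start[-1]) <= prefix_key(out$end[-nrow(out)]))
  if (length(overlap)) {
    abort(sprintf("overlapping block ranges '%s' and '%s'",
                  out$block_id[overlap[1]], out$block_id[overlap[1] + 1]),
          "edrisk_parse_error")
  }
  rownames(out) <- NULL
  class(out) <- c("block_table", "data.frame")
  out
}

#' The packaged WHO ICD-10 block table
#'
#' The block structure of the WHO ICD-10 (2019) tabular list: 255 blocks
#' across chapters I-XXII, shipped as a plain-text fixture. Users may supply
#' their own table to any function accepting `blocks`.
#'
#' @return a `block_table` data frame.
#' @export
icd10_blocks <- function() {
  parse_block_table(system.file("extdata", "icd10_blocks.csv",
                                package = "edrisk", mustWork = TRUE))
}

#' Map ICD-10 codes to blocks
#'
#' A code belongs to the block whose range contains its first three
#' characters (upper-cased), compared lexicographically. Codes outside every
#' range map to `NA` ("unmapped"), which callers handle by policy.
#'
#' @param code character vector of ICD-10 codes.
#' @param blocks a `block_table`.
#' @return character vector of block ids (`NA` where unmapped).
#' @export
code_to_block <- function(code, blocks) {
  stopifnot(inherits(blocks, "block_table"))
  prefix <- toupper(substr(trimws(code), 1, 3))
  if (nrow(blocks) == 0) return(rep(NA_character_, length(code)))
  key <- prefix_key(prefix)
  idx <- findInterval(key, prefix_key(blocks$start))
  hit <- !is.na(key) & idx >= 1
  hit[hit] <- key[hit] <= prefix_key(blocks$end)[idx[hit]]
  out <- rep(NA_character_, length(code))
  out[hit] <- blocks$block_id[idx[hit]]
  out
}

# numeric sort key for a 3-character ICD-10 prefix: letter rank * 100 + digits
prefix_key <- function(prefix) {
  ok <- grepl("^[A-Z][0-9]{2}$", prefix)
  key <- rep(NA_real_, length(prefix))
  key[ok] <- (match(substr(prefix[ok], 1, 1), LETTERS) - 1) * 100 +
    as.integer(substr(prefix[ok], 2, 3))
  key
}

#' Summarize cluster composition per ICD-10 block
#'
#' Counts presentations per block and risk cluster, derives per-block cluster
#' proportions, and identifies each block's dominant cluster (argmax
#' proportion, ties to the lower label).
#'
#' @param records registry data frame with a `cluster` column (see
#'   [propagate_clusters()]).
#' @param blocks a `block_table`.
#' @param unmapped policy for codes outside the table: `"error"` (default) or
#'   `"collect"` into an `"UNMAPPED"` pseudo-block.
#' @param basis unit for counts and proportions: `"presentations"` (default)
#'   counts ED visits, `"codes"` counts distinct member codes per cluster.
#' @return object of class `block_summary`: list with `summary` (one row per
#'   block: `block_id`, `n_presentations`, `dominant_cluster`,
#'   `dominant_proportion`), `counts` and `proportions` (block x cluster
#'   matrices) and `k`.
#' @export
summarize_blocks <- function(records, blocks = icd10_blocks(),
                             unmapped = c("error", "collect"),
                             basis = c("presentations", "codes")) {
  unmapped <- match.arg(unmapped)
  basis <- match.arg(basis)
  stopifnot("cluster" %in% names(records))
  if (basis == "codes") {
    records <- unique(records[c("icd10", "cluster")])
  }
  block <- code_to_block(records$icd10, blocks)
  if (anyNA(block)) {
    if (unmapped == "error") {
      offending <- sort(unique(records$icd10[is.na(block)]))
      abort(paste0("unmapped codes under strict policy: ",
                   paste(offending, collapse = ", ")), "edrisk_domain_error")
    }
    block[is.na(block)] <- "UNMAPPED"
  }
  k <- max(records$cluster)
  counts <- table(factor(block), factor(records$cluster, levels = seq_len(k)))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"
  props <- counts / rowSums(counts)
  dom <- apply(props, 1, which.max) # which.max ties -> first (lower label)
  structure(list(
    summary = data.frame(
      block_id = rownames(counts),
      n_presentations = as.integer(rowSums(counts)),
      dominant_cluster = as.integer(dom),
      dominant_proportion = props[cbind(seq_len(nrow(props)), dom)],
      stringsAsFactors = FALSE, row.names = NULL
    ),
    counts = counts, proportions = props, k = as.integer(k)
  ), class = "block_summary")
}

#' Cumulative-coverage curve over ICD-10 blocks
#'
#' Ranks blocks by presentation count (descending; ties alphabetical by
#' block id) and reports, for each coverage threshold, the smallest number of
#' top-ranked blocks whose cumulative share of presentations reaches it.
#'
#' @param block_summary a [summarize_blocks()] result.
#' @param thresholds coverage fractions in `(0, 1]`.
#' @return object of class `coverage_curve`: list with `ranked` (rank,
#'   block_id, n, share, cumulative_share) and `blocks_at_threshold` (named
#'   integer vector).
#' @export
cumulative_coverage <- function(block_summary,
                                thresholds = c(0.6, 0.7, 0.8, 0.9, 1)) {
  stopifnot(inherits(block_summary, "block_summary"))
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("coverage thresholds must lie in (0, 1]", "edrisk_domain_error")
  }
  s <- block_summary$summary
  ord <- order(-s$n_presentations, s$block_id)
  n <- s$n_presentations[ord]
  share <- n / sum(n)
  cum <- cumsum(share)
  at <- vapply(thresholds, function(t) which(cum >= t - 1e-12)[1], integer(1))
  names(at) <- format(thresholds)
  structure(list(
    ranked = data.frame(rank = seq_along(ord), block_id = s$block_id[ord],
                        n = n, share = share, cumulative_share = cum,
                        stringsAsFactors = FALSE),
    blocks_at_threshold = at
  ), class = "coverage_curve")
}

#' Blocks dominated by a single risk cluster
#'
#' Filters block summaries to those whose dominant-cluster proportion reaches
#' `min_representation` (>= comparison), optionally restricted to a given
#' dominant cluster, and reports the presentations they account for and that
#' total's share of the registry (1 decimal, half-up).
#'
#' @param block_summary a [summarize_blocks()] result.
#' @param min_representation dominance threshold in `(0, 1]`; default 0.75.
#' @param cluster optional cluster label to restrict to.
#' @return list with `blocks` (the qualifying summary rows),
#'   `n_presentations`, `registry_total` and `share_pct`.
#' @export
dominant_blocks <- function(block_summary, min_representation = 0.75,
                            cluster = NULL) {
  stopifnot(inherits(block_summary, "block_summary"))
  if (min_representation <= 0 || min_representation > 1) {
    abort("min_representation must lie in (0, 1]", "edrisk_domain_error")
  }
  s <- block_summary$summary
  keep <- s$dominant_proportion >= min_representation
  if (!is.null(cluster)) keep <- keep & s$dominant_cluster == cluster
  total <- sum(s$n_presentations)
  sel <- s[keep, , drop = FALSE]
  rownames(sel) <- NULL
  list(blocks = sel,
       n_presentations = sum(sel$n_presentations),
       registry_total = total,
       share_pct = round_half_up(100 * sum(sel$n_presentations) / total, 1))
}

#' Heatmap matrix of cluster proportions for the top-coverage blocks
#'
#' Restricts blocks to those within the cumulative-coverage threshold, groups
#' rows by ICD-10 chapter, and returns the block-by-cluster proportion matrix
#' (each row sums to 1) ready for any plotting layer.
#'
#' @param block_summary a [summarize_blocks()] result.
#' @param blocks the `block_table` (supplies chapter grouping).
#' @param coverage_threshold coverage fraction in `(0, 1]`; default 0.8.
#' @return numeric matrix (blocks x clusters) with a `chapter` attribute
#'   giving each row's chapter.
#' @export
heatmap_matrix <- function(block_summary, blocks = icd10_blocks(),
                           coverage_threshold = 0.8) {
  cov <- cumulative_coverage(block_summary, coverage_threshold)
  n_top <- cov$blocks_at_threshold[[1]]
  top <- cov$ranked$block_id[seq_len(n_top)]
  if (length(top) == 0) {
    abort("coverage threshold excludes all blocks", "edrisk_domain_error")
  }
  chapter <- blocks$chapter[match(top, blocks$block_id)]
  chapter[is.na(chapter)] <- "ZZZ (unmapped)"
  ord <- order(chapter, top)
  m <- block_summary$proportions[top[ord], , drop = FALSE]
  colnames(m) <- paste0("cluster_", seq_len(ncol(m)))
  attr(m, "chapter") <- chapter[ord]
  m
}
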