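# shared fixtures: small registries, toy block tables, naive index oracles

small_sim <- function(n = 5000L, seed = 1L, ...) {
  sim_config(n_presentations = as.integer(n), seed = as.integer(seed), ...)
}

# hand-rolled registry rows for unit tests
toy_records <- function(icd10, admitted = 0L, n_each = 1L, ...) {
  rows <- data.frame(
    id = sprintf("T%04d", seq_len(length(icd10) * n_each)),
    icd10 = rep(icd10, each = n_each),
    admitted = rep_len(as.integer(admitted), length(icd10) * n_each),
    age = 40L, sex = "female", ethnicity = "Chinese",
    sbp = 120L, pulse = 75L, temp = 36.8, cci = 0L,
    prior_ed = 0L, prior_inpt = 0L, prior_surg = 0L, prior_icu = 0L,
    prior_hd = 0L, prior_ica = 0L, prior_infect = 0L,
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) rows[[nm]] <- extra[[nm]]
  rows
}

write_toy_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  header <- paste(c("id", "icd10", "admitted", "age", "sex", "ethnicity",
                    "sbp", "pulse", "temp", "cci", "prior_ed", "prior_inpt",
                    "prior_surg", "prior_icu", "prior_hd", "prior_ica",
                    "prior_infect"), collapse = ",")
  writeLines(c(header, lines), path)
  path
}

toy_block_table <- function(rows = c("A00-A09,Intestinal infectious diseases,I",
                                     "J09-J18,Influenza and pneumonia,X")) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("block_id,title,chapter", rows), path)
  parse_block_table(path)
}

# build a block_summary object directly from per-block cluster counts
manual_block_summary <- function(counts) { # counts: named list block -> vector
  m <- do.call(rbind, counts)
  rownames(m) <- names(counts)
  colnames(m) <- seq_len(ncol(m))
  props <- m / rowSums(m)
  dom <- apply(props, 1, which.max)
  structure(list(
    summary = data.frame(block_id = rownames(m),
                         n_presentations = as.integer(rowSums(m)),
                         dominant_cluster = as.integer(dom),
                         dominant_proportion = props[cbind(seq_len(nrow(m)), dom)],
                         stringsAsFactors = FALSE, row.names = NULL),
    counts = m, proportions = props, k = ncol(m)
  ), class = "block_summary")
}

# --- independent oracles -----------------------------------------------------

# exhaustive search over contiguous partitions of the sorted values
brute_force_wcss <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  sse <- function(x) sum((x - mean(x))^2)
  if (k == 1) return(sse(v))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(m) sse(v[(b[m] + 1):b[m + 1]]),
                      numeric(1)))
    best <- min(best, tot)
  }
  best
}

# per-definition silhouette with plain loops
naive_silhouette <- function(v, lab) {
  n <- length(v)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab == lab[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(abs(v[i] - v[own & seq_len(n) != i]))
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(abs(v[i] - v[lab == g])), numeric(1)))
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  list(mean = mean(s), scores = s)
}

naive_ch <- function(v, lab) {
  ks <- unique(lab); k <- length(ks); n <- length(v)
  cen <- sapply(ks, function(g) mean(v[lab == g]))
  B <- sum(sapply(seq_along(ks), function(i)
    sum(lab == ks[i]) * (cen[i] - mean(v))^2))
  W <- sum(sapply(seq_along(ks), function(i) sum((v[lab == ks[i]] - cen[i])^2)))
  (B / (k - 1)) / (W / (n - k))
}

naive_db <- function(v, lab) {
  ks <- unique(lab); k <- length(ks)
  cen <- sapply(ks, function(g) mean(v[lab == g]))
  s <- sapply(seq_along(ks), function(i) mean(abs(v[lab == ks[i]] - cen[i])))
  mean(sapply(seq_len(k), function(i)
    max(sapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / abs(cen[i] - cen[j])))))
}

# labelled values with at least 2 clusters, for random index instances
random_labelled_instance <- function(n = NULL, k = NULL) {
  n <- n %||% sample(6:30, 1)
  k <- k %||% sample(2:4, 1)
  v <- stats::runif(n)
  lab <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
  # guard against coincident centroids (Davies-Bouldin undefined)
  cen <- sapply(seq_len(k), function(g) mean(v[lab == g]))
  if (anyDuplicated(cen)) return(random_labelled_instance(n, k))
  list(v = v, lab = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
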