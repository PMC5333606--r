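# Binary entropy in bits; H2(0) = H2(1) = 0 by convention.
binary_entropy <- function(p) {
  out <- numeric(length(p))
  inside <- p > 0 & p < 1
  q <- p[inside]
  out[inside] <- -q * log2(q) - (1 - q) * log2(1 - q)
  out
}

# All unordered feature pairs {k, l} with k < l in index order.
pair_index <- function(n_f) {
  k <- rep.int(seq_len(n_f - 1L), times = (n_f - 1L):1L)
  l <- unlist(lapply(seq_len(n_f - 1L), function(i) (i + 1L):n_f), use.names = FALSE)
  list(k = k, l = l)
}

# Feature columns of a cohort table: everything except the id and label.
feature_names_of <- function(cohort, label_col = "DEATH") {
  setdiff(names(cohort), c("subject_id", label_col))
}

check_label <- function(cohort, label_col) {
  if (!label_col %in% names(cohort)) {
    abort(paste0("label column '", label_col, "' not found"))
  }
  lab <- cohort[[label_col]]
  if (!all(lab %in% c(0, 1))) {
    abort(paste0("label column '", label_col, "' must contain only 0 and 1"))
  }
  as.integer(lab)
}
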