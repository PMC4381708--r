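# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately re-derive results from first
# principles (explicit loops, pairwise comparisons) rather than reusing any
# package code path.

# UPGMA by direct enumeration: at every step recompute the mean cross-pair
# distance of every cluster pair and merge the minimum. Returns the merge
# heights in merge order.
upgma_oracle_heights <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(dm[clusters[[i]], clusters[[j]]])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Lexicographic probe selection by explicit pairwise comparison.
# cand: data frame with probe_id, reliable, suffix_rank, mean_intensity.
lex_select_oracle <- function(cand, use_calls = TRUE) {
  better <- function(a, b) {
    if (use_calls) {
      if (a$reliable != b$reliable) return(a$reliable)
      if (a$suffix_rank != b$suffix_rank) return(a$suffix_rank < b$suffix_rank)
    }
    if (a$mean_intensity != b$mean_intensity)
      return(a$mean_intensity > b$mean_intensity)
    a$probe_id < b$probe_id
  }
  best <- cand[1, ]
  for (i in seq_len(nrow(cand))[-1])
    if (better(cand[i, ], best)) best <- cand[i, ]
  best$probe_id
}

# Expression table in which each probe has a constant signal (its intended
# mean intensity) and all-P or all-A calls encoding its reliability.
probe_table_from_scores <- function(cand, n_samples = 4) {
  sig <- matrix(rep(cand$mean_intensity, each = n_samples),
                nrow = nrow(cand), byrow = TRUE,
                dimnames = list(cand$probe_id, paste0("s", seq_len(n_samples))))
  calls <- matrix(rep(ifelse(cand$reliable, "P", "A"), each = n_samples),
                  nrow = nrow(cand), byrow = TRUE, dimnames = dimnames(sig))
  expression_table(sig, calls)
}

# Random selection instance: <= 8 candidates with random suffixes,
# reliability and intensities (occasional exact intensity ties).
random_selection_instance <- function() {
  k <- sample(2:8, 1)
  suffix <- sample(c("_at", "_s_at", "_x_at", ""), k, replace = TRUE)
  ids <- paste0(sprintf("%03d", sample(999, k)), suffix)
  while (anyDuplicated(ids))
    ids <- paste0(sprintf("%03d", sample(999, k)), suffix)
  intensity <- round(stats::runif(k, 10, 1000), ifelse(stats::runif(k) < 0.3, -1, 2))
  data.frame(probe_id = ids,
             reliable = sample(c(TRUE, FALSE), k, replace = TRUE),
             suffix_rank = as.integer(probe_suffix_class(ids)) - 1L,
             mean_intensity = intensity,
             stringsAsFactors = FALSE)
}

# Small gene-level table with planted tumor/normal structure for clustering.
planted_gene_table <- function(n_patients = 6, n_genes = 30, effect = 2,
                               noise = 0.1, seed = 42) {
  set.seed(seed)
  patients <- sprintf("p%02d", seq_len(n_patients))
  base <- matrix(stats::rnorm(n_genes * n_patients, 6, 1), nrow = n_genes)
  shift <- stats::rnorm(n_genes, 0, effect)
  tum <- exp(base + shift + stats::rnorm(n_genes * n_patients, 0, noise))
  nor <- exp(base + stats::rnorm(n_genes * n_patients, 0, noise))
  sig <- cbind(tum, nor)
  dimnames(sig) <- list(sprintf("g%03d", seq_len(n_genes)),
                        c(paste0(patients, "_T"), paste0(patients, "_N")))
  list(table = expression_table(sig),
       pairing = sample_pairing(data.frame(patient = patients,
                                           tumor = paste0(patients, "_T"),
                                           normal = paste0(patients, "_N"),
                                           stringsAsFactors = FALSE)))
}

write_toy_expression <- function(path, with_calls = TRUE) {
  lines <- if (with_calls) c(
    "probe_id\ts1\ts1_call\ts2\ts2_call",
    "1000_at\t120.5\tP\t80.25\tA",
    "1001_s_at\t15\tA\t300\tP"
  ) else c(
    "probe_id\ts1\ts2",
    "1000_at\t120.5\t80.25",
    "1001_s_at\t15\t300"
  )
  writeLines(lines, path)
  path
}
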