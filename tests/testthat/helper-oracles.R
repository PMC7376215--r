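# Independent oracles: deliberately naive direct-definition implementations
# used to cross-check the package's vectorized/closed-form code paths.

# O(m^2) Benjamini-Hochberg straight from the step-up definition
bh_oracle <- function(p) {
  obs <- which(!is.na(p))
  m <- length(obs)
  q <- rep(NA_real_, length(p))
  for (i in obs) {
    # q_i = min over k with p_k >= p_i (rank >= rank_i) of p_k * m / rank_k
    ranks <- rank(p[obs], ties.method = "first")
    ri <- ranks[match(i, obs)]
    cand <- Inf
    for (j in seq_along(obs)) {
      if (ranks[j] >= ri) {
        cand <- min(cand, p[obs[j]] * m / ranks[j])
      }
    }
    q[i] <- min(cand, 1)
  }
  q
}

# hypergeometric upper tail by direct summation
hyper_tail_oracle <- function(k, K, n, N) {
  if (K == 0) return(1)
  jmax <- min(K, n)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j) {
    choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }, 0))
}

# brute-force NB MLE log2 fold change for a two-group design with offsets:
# each group mean maximized independently by 1-D golden-section search
nb_mle_oracle <- function(y, sf, groups, alpha) {
  loglik <- function(logm, yy, ss) {
    mu <- exp(logm) * ss
    if (alpha > 0) sum(stats::dnbinom(yy, mu = mu, size = 1 / alpha, log = TRUE))
    else sum(stats::dpois(yy, mu, log = TRUE))
  }
  ms <- vapply(unique(groups), function(g) {
    sel <- groups == g
    stats::optimize(loglik, c(-15, 20), yy = y[sel], ss = sf[sel],
                    maximum = TRUE, tol = 1e-10)$maximum
  }, 0)
  (ms[2] - ms[1]) / log(2)
}

# brute-force UPGMA (average linkage): returns sorted merge heights
avg_linkage_heights_oracle <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          dd <- mean(d[clusters[[i]], clusters[[j]]])
          if (dd < bestd) {
            bestd <- dd
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# brute-force induced-set rule by direct per-transcript enumeration
induced_oracle <- function(exposed, control, ratio_threshold) {
  out <- character(0)
  prov <- character(0)
  for (id in exposed$members$transcript_id) {
    le <- exposed$members$log2fc[exposed$members$transcript_id == id]
    in_ctl <- id %in% control$members$transcript_id
    if (!in_ctl) {
      out <- c(out, id)
      prov <- c(prov, "unique")
    } else {
      lc <- control$members$log2fc[control$members$transcript_id == id]
      if (2^le / 2^lc > ratio_threshold) {
        out <- c(out, id)
        prov <- c(prov, "ratio")
      }
    }
  }
  ord <- order(out)
  data.frame(transcript_id = out[ord], provenance = prov[ord],
             stringsAsFactors = FALSE)
}

# a sim_config with planted sets scaled down proportionally to n
small_cfg <- function(n, ...) {
  sim_config(n_transcripts = n,
             n_enriched_exposed_only = round(0.05 * n),
             n_enriched_both = round(0.025 * n),
             n_de_up = round(0.025 * n), n_de_down = round(0.025 * n), ...)
}

# small helpers for fixtures
make_enriched <- function(ids, lfc, condition = "exposed") {
  k <- length(ids)
  tab <- data.frame(transcript_id = as.character(ids),
                    base_mean = rep(100, k), log2fc = as.numeric(lfc),
                    se = rep(0.1, k), stat = as.numeric(lfc) / 0.1,
                    pvalue = rep(1e-6, k), padj = rep(1e-5, k),
                    stringsAsFactors = FALSE)
  enriched_set(tab, condition = condition, padj_max = 0.1, min_fc = 2)
}

tiny_counts <- function(mat, conditions, fractions, replicates = NULL) {
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(conditions),
                             paste(conditions, fractions), FUN = seq_along)
  }
  ids <- paste0("s", seq_along(conditions))
  colnames(mat) <- ids
  rip_counts(mat, sample_sheet(ids, conditions, fractions, replicates))
}
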