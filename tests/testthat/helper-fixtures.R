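# Fixtures built in code: tiny designs, pools and oracle implementations
# shared across test files.

# Design with a known synonymous pair (TCT/TCC both serine) at L3 position 1.
synonymous_design <- function() {
  library_design(
    cdrs = list(
      L3 = list(lengths = 3, positions = list(
        "3" = list(c("TCT", "TCC"), c("TAT", "TCT"), c("TAT", "TCT"))
      )),
      H1 = list(lengths = 2, codon_set = c("TAT", "TCT")),
      H2 = list(lengths = 2, codon_set = c("TAT", "TCT")),
      H3 = list(lengths = 2, codon_set = c("TAT", "TCT", "TGG"))
    ),
    anchors = list(
      L3 = list(left = "GGTTCTAC", right = "TTCGGCCA"),
      H1 = list(left = "TTCGGCCA", right = "TGGGTGCG"),
      H2 = list(left = "TGGGTGCG", right = "CGTTTCAC"),
      H3 = list(left = "CGTTTCAC", right = "TGGGGTCA")
    )
  )
}

# A pool whose entries are handed in directly (h3-focused tests use dummy
# values for the other CDRs).
make_pool <- function(h3, count = 1, l3 = "SSS", h1 = "YY", h2 = "SS",
                      label = "positive") {
  selection_pool(
    tibble::tibble(
      l3 = rep_len(l3, length(h3)), h1 = rep_len(h1, length(h3)),
      h2 = rep_len(h2, length(h3)), h3 = h3,
      count = rep_len(count, length(h3))
    ),
    label
  )
}

# Exhaustive O(n^2) maximizer of between-class inertia over sorted splits;
# the independent oracle for kh_cutoff.
bf_kh_cutoff <- function(values) {
  v <- sort(values)
  n <- length(v)
  if (n < 2 || v[1] == v[n]) return(NA_real_)
  best <- -Inf
  bi <- NA_integer_
  for (k in 1:(n - 1)) {
    m1 <- mean(v[1:k])
    m2 <- mean(v[(k + 1):n])
    b <- k * (n - k) / n * (m1 - m2)^2
    if (b > best) {
      best <- b
      bi <- k
    }
  }
  (v[bi] + v[bi + 1]) / 2
}

# Naive 2^L motif enumeration with support and polymorphism constraints;
# the independent oracle for enumerate_motifs. `seqs` are the positive
# pool's unique sequences of the candidate's length.
bf_motifs <- function(cand, seqs, min_support, max_frac = 0.55, poly = TRUE) {
  L <- nchar(cand)
  kmax <- floor(max_frac * L)
  cand_ch <- strsplit(cand, "")[[1]]
  seq_mat <- do.call(rbind, strsplit(seqs[nchar(seqs) == L], ""))
  out <- character(0)
  for (mask in 0:(2^L - 1)) {
    w <- which(bitwAnd(mask, 2^(seq_len(L) - 1)) > 0)
    if (length(w) > kmax) next
    pat <- cand_ch
    pat[w] <- "X"
    def <- setdiff(seq_len(L), w)
    hit <- rep(TRUE, nrow(seq_mat))
    for (p in def) hit <- hit & seq_mat[, p] == cand_ch[p]
    if (sum(hit) < min_support) next
    if (poly && length(w) > 0) {
      ok <- all(vapply(w, function(p) {
        length(unique(seq_mat[hit, p])) > 1
      }, logical(1)))
      if (!ok) next
    }
    out <- c(out, paste(pat, collapse = ""))
  }
  out
}

# Direct numerical integration of the Student-t density (Gamma-function
# normalization in log space); the quadrature oracle for t_tail_p.
bf_t_upper_tail <- function(t, f) {
  dens <- function(x) {
    exp(lgamma((f + 1) / 2) - lgamma(f / 2) - 0.5 * log(f * pi) -
      (f + 1) / 2 * log1p(x^2 / f))
  }
  stats::integrate(dens, t, Inf, rel.tol = 1e-13, abs.tol = 0)$value
}

# Brute-force single-linkage families on L3+H3 identity.
bf_families <- function(clones, thr) {
  n <- nrow(clones)
  s <- paste0(clones$l3, clones$h3)
  member <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (i in seq_along(member)) {
      for (j in seq_along(member)) {
        if (j <= i) next
        link <- FALSE
        for (a in member[[i]]) {
          for (b in member[[j]]) {
            idn <- 1 - utils::adist(s[a], s[b])[1, 1] / max(nchar(s[a]), nchar(s[b]))
            if (idn >= thr) link <- TRUE
          }
        }
        if (link) {
          member[[i]] <- c(member[[i]], member[[j]])
          member <- member[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  comp <- integer(n)
  for (k in seq_along(member)) comp[member[[k]]] <- k
  comp
}

# Small, fast simulation used across tests.
small_sim_config <- function(seed, chimera_rate = 0.05, ...) {
  simulation_config(
    n_specific_families = 2, clones_per_family = 150, n_background = 1200,
    reads_per_pool = 2e5, chimera_rate = chimera_rate, seed = seed, ...
  )
}
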