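# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation paths they check.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All-substrings scan for restriction motif starts (0-based cut positions).
naive_cut_sites <- function(s, motif = "CCGG", offset = 1L) {
  L <- nchar(s); m <- nchar(motif)
  hits <- integer(0)
  for (p in seq_len(L - m + 1L))
    if (substr(s, p, p + m - 1L) == motif) hits <- c(hits, p - 1L + offset)
  hits
}

# Per-column classification by direct enumeration.
naive_classify_column <- function(col) {
  states <- col[!col %in% c("-", "N")]
  tab <- table(states)
  if (length(tab) <= 1L) return("constant")
  if (sum(tab >= 2L) >= 2L) return("PI")
  "VU"
}

# Gotoh global affine alignment score (gap of length L costs open + L*ext).
gotoh_score <- function(a, b, match, mismatch, open, ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (ca[i] == cb[j]) match else mismatch
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                           X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                           X[i + 1, j] - open - ext,
                           Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Double-loop step/compared-site counts for one sequence pair.
naive_steps <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  ok <- !(c1 %in% c("-", "N")) & !(c2 %in% c("-", "N"))
  c(steps = sum(c1[ok] != c2[ok]), compared = sum(ok))
}

make_aln <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  multiple_alignment(Map(seq_record, ids, seqs))
}

make_clones <- function(seqs, individual = "ind1", prefix = "c") {
  lapply(seq_along(seqs), function(i)
    seq_record(paste0(individual, "_", prefix, i), seqs[i],
               marker = "ITS2", individual = individual))
}

# Small shared simulations, built once per test file that asks for them.
.sim_store <- new.env(parent = emptyenv())
cached_sim <- function(key, cfg, requests = NULL) {
  if (is.null(.sim_store[[key]]))
    .sim_store[[key]] <- simulate_dataset(cfg, requests)
  .sim_store[[key]]
}
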