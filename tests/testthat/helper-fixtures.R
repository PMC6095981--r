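# Shared fixtures and independent oracles used across test files.

# small cached germline set; tests that need other sizes build their own
test_germline <- local({
  gs <- NULL
  function() {
    if (is.null(gs)) gs <<- make_germline_set(6, 3, 2, seed = 42)
    gs
  }
})

# --- independent oracles -----------------------------------------------

# brute-force O(n^2) Hamming distance (pure R, no early exit)
r_hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(charToRaw(a) != charToRaw(b))
}

# brute-force clusters: all-pairs Hamming-1 adjacency + label propagation
r_brute_clusters <- function(seqs) {
  n <- length(seqs)
  labels <- seq_len(n)
  adj <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- r_hamming(seqs[i], seqs[j])
      if (!is.na(d) && d == 1L) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in adj[[i]]) {
        if (labels[j] > labels[i]) { labels[j] <- labels[i]; changed <- TRUE }
        if (labels[i] > labels[j]) { labels[i] <- labels[j]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  labels
}

# partition equality irrespective of label names
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}

# brute-force shared-k-mer score between a read segment and a gene prefix
r_kmer_score <- function(segment, gene_prefix, k = 10L) {
  wins <- function(s) substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  sum(wins(gene_prefix) %in% wins(segment))
}

# random mutated copy of a sequence (no stop-codon safety; raw oracle use)
mutate_raw <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# quick AIRR-style table constructor for stats tests
mk_tab <- function(sequence, c_call, duplicate_count = 1L, v_call = "IGHV1-x",
                   j_call = "IGHJ1-x", junction_aa = "CARW", n_mut_total = 0L,
                   n_mut_silent = 0L, n_mut_nonsilent = 0L,
                   sample_id = "s1") {
  data.table::data.table(
    sequence_id = sprintf("r%03d", seq_along(sequence)),
    sequence = sequence, c_call = c_call,
    duplicate_count = duplicate_count, v_call = v_call, j_call = j_call,
    junction_aa = junction_aa, n_mut_total = n_mut_total,
    n_mut_silent = n_mut_silent, n_mut_nonsilent = n_mut_nonsilent,
    sample_id = sample_id)
}
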