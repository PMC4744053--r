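# Shared fixtures: tiny datasets built in code, plus independent oracle
# implementations used to cross-check the package's algorithms.

toy_meta <- function(ids, species = ids, genus = "GenusA",
                     tribe = "TribeA") {
  data.frame(sample_id = ids, morphospecies = species,
             genus = rep_len(genus, length(ids)),
             tribe = rep_len(tribe, length(ids)),
             country = "KR", province = "GW", source = "field",
             stringsAsFactors = FALSE)
}

# stop-free coding sequence of length 658 built from CTT (Leu) codons,
# frame offset 1 (leading A)
leucine_seq <- function(len = 658L) {
  paste0("A", paste(rep("CTT", (len - 1L) %/% 3L), collapse = ""),
         substr("CTT", 1L, (len - 1L) %% 3L))
}

toy_dataset <- function(n = 3L, len = 658L, mutate_at = NULL) {
  base <- strsplit(leucine_seq(len), "")[[1L]]
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    if (!is.null(mutate_at))
      for (p in mutate_at[[min(i, length(mutate_at))]])
        s[p] <- c(A = "G", C = "T", G = "A", T = "C")[s[p]]
    paste(s, collapse = "")
  }, "")
  names(seqs) <- sprintf("seq%02d", seq_len(n))
  barcode_dataset(seqs, toy_meta(names(seqs)))
}

# distance matrix object wrapping an explicit symmetric matrix
fake_dm <- function(m, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(m)))
  dimnames(m) <- NULL
  structure(list(ids = ids, values = m, model = "k2p",
                 comparable_sites = matrix(658L, nrow(m), nrow(m)),
                 min_sites = 100L),
            class = "barcode_dist")
}

random_symmetric <- function(n, max_d = 0.2) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0, max_d)
  m + t(m)
}

small_sim <- function(n_species = 4L, n_per = 4L, intra = 0.005,
                      inter = 0.10, seed = 1L, ...) {
  sp <- lapply(seq_len(n_species), function(i)
    species_spec(sprintf("Sp%02d", i), n_per, intra,
                 genus = sprintf("G%02d", (i + 1L) %/% 2L), tribe = "T1"))
  sim_config(sp, target_inter_congeneric = inter, seed = seed,
             inter_genus = max(0.198, inter * 1.5),
             inter_tribe = max(0.202, inter * 1.55), ...)
}
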