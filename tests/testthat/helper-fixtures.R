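# In-code fixtures shared across test files.

# small ABH dataset: identical clear-cut columns, optional parents
toy_abh <- function(n_markers = 4, pattern = c("A", "A", "A", "A", "B", "B", "B", "B"),
                    parents = TRUE, generation = 8) {
  geno <- matrix(rep(pattern, n_markers), length(pattern), n_markers)
  colnames(geno) <- paste0("m", seq_len(n_markers))
  rownames(geno) <- paste0("i", seq_len(length(pattern)))
  par <- if (parents) {
    rbind(
      P1 = rep("A", n_markers),
      P2 = rep("B", n_markers)
    )
  } else {
    NULL
  }
  pop_data(geno, coding = "ABH", generation = generation, parents = par)
}

toy_map <- function(markers, spacing = 5, group = "LG1") {
  genetic_map(markers, rep(group, length(markers)),
    pos_cM = spacing * (seq_along(markers) - 1)
  )
}

# classify a two-marker token pair into the nine two-locus genotype labels
# used by two_locus_genotype_distribution (A = parent-1 homozygote)
abh_pair_label <- function(tok1, tok2) {
  l1 <- c(A = "AA", H = "Aa", B = "aa")[tok1]
  l2 <- c(A = "BB", H = "Bb", B = "bb")[tok2]
  paste0(l1, l2)
}
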