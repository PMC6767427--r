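## fixtures are built in code at test time

## a ComparisonData assembled directly from per-locus site matrices
makeComparison <- function(loci, label = "toy",
                           populations = c("pop1", "pop2"),
                           variable = NULL) {
  loci <- lapply(loci, function(l) {
    m <- matrix(as.integer(l), ncol = 4,
                dimnames = list(NULL, c("n1", "n2", "r1", "r2")))
    m
  })
  if (is.null(variable))
    variable <- sum(vapply(loci, function(l) sum(l[, "r1"] + l[, "r2"] > 0), 0L))
  codivtimes:::newComparisonData(
    label, populations,
    structure(populations, names = paste0(label, c("_a", "_b"))),
    loci, variable = variable, polyallelic = 0L, droppedEmpty = 0L)
}

## write a toy per-locus FASTA directory; seqs is a list of named character
## vectors (one per locus), each element a sequence string
writeToyFasta <- function(seqs, dir = tempfile("loci")) {
  dir.create(dir)
  for (i in seq_along(seqs)) {
    con <- file.path(dir, sprintf("locus%02d.fasta", i))
    writeLines(as.vector(rbind(paste0(">", names(seqs[[i]])), seqs[[i]])), con)
  }
  dir
}

toyPopMap <- function(ids1 = c("s1", "s2"), ids2 = c("s3", "s4"),
                      label = "toy") {
  populationMap(label, c("pop1", "pop2"),
                structure(rep(c("pop1", "pop2"),
                              c(length(ids1), length(ids2))),
                          names = c(ids1, ids2)))
}

## enumerate all set partitions of n items (oracle for small n)
enumeratePartitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enumeratePartitions(n - 1)) {
    k <- max(p)
    for (e in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, e)
  }
  out
}
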