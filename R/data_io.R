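## Reading multilocus alignments, binary recoding, pattern compression.

MISSING_SYMBOLS <- c("-", "N", "?", ".", "n")

#' Recode an alignment column to a biallelic site pattern
#'
#' State 0 is the first non-missing nucleotide scanning the column
#' top-to-bottom in input order; state 1 is any other nucleotide.  Columns
#' with three or more nucleotides (polyallelic sites) are either removed or
#' merged into state 1, depending on `mode`.  Missing symbols (`-`, `N`,
#' `?`, `.`) reduce the per-population sampled copy count.
#'
#' @param column character vector of nucleotide symbols, in alignment
#'   order.
#' @param population character/factor of the same length giving each
#'   sequence's population; must have exactly two levels, in the order of
#'   the comparison's population labels.
#' @param mode "remove" or "recode".
#' @return a list: either
#'   `list(status = "ok", n1, n2, r1, r2, polyallelic = TRUE/FALSE)` or
#'   `list(status = "removed", reason = "polyallelic" | "all_missing")`.
#' @examples
#' recodeBiallelic(c("A", "G", "T", "A"), c(1, 1, 2, 2), mode = "recode")
#' @export
recodeBiallelic <- function(column, population, mode = c("remove", "recode")) {
  mode <- match.arg(mode)
  column <- toupper(as.character(column))
  ok <- !(column %in% toupper(MISSING_SYMBOLS))
  if (!any(ok)) return(list(status = "removed", reason = "all_missing"))
  states <- unique(column[ok])
  poly <- length(states) >= 3
  if (poly && mode == "remove")
    return(list(status = "removed", reason = "polyallelic"))
  first <- column[ok][1]
  isOne <- ok & column != first
  pop <- if (is.factor(population)) population
         else factor(population, levels = unique(population))
  if (nlevels(pop) > 2) stop("more than two populations in column")
  p1 <- as.integer(pop) == 1L
  list(status = "ok",
       n1 = sum(ok & p1), n2 = sum(ok & !p1),
       r1 = sum(isOne & p1), r2 = sum(isOne & !p1),
       polyallelic = poly)
}

## canonical orientation: state 1 is the rarer state overall; on ties the
## lexicographically smaller (r1, r2) wins.  The likelihood is invariant
## under the flip r -> n - r, and the canonical form makes pattern tables
## unique (and write/read round trips exact).
canonicalizeSite <- function(n1, n2, r1, r2) {
  f1 <- n1 - r1; f2 <- n2 - r2
  flip <- (r1 + r2 > f1 + f2) ||
    (r1 + r2 == f1 + f2 && (r1 > f1 || (r1 == f1 && r2 > f2)))
  if (flip) c(n1, n2, f1, f2) else c(n1, n2, r1, r2)
}

compressPatterns <- function(loci) {
  all <- do.call(rbind, loci)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(n1 = integer(), n2 = integer(), r1 = integer(),
                      r2 = integer(), weight = numeric()))
  }
  key <- paste(all[, 1], all[, 2], all[, 3], all[, 4])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  out <- data.frame(n1 = as.integer(parts[, 1]), n2 = as.integer(parts[, 2]),
                    r1 = as.integer(parts[, 3]), r2 = as.integer(parts[, 4]),
                    weight = as.numeric(tab))
  out[order(out$n1, out$n2, out$r1, out$r2), , drop = FALSE]
}

## assemble a ComparisonData from per-locus site matrices (already canonical)
newComparisonData <- function(label, populations, sampleMap, loci,
                              variable, polyallelic, droppedEmpty) {
  sites <- sum(vapply(loci, nrow, 0L))
  new("ComparisonData", label = label, populations = populations,
      sampleMap = sampleMap, loci = loci,
      patterns = compressPatterns(loci),
      counts = c(loci = length(loci), sites = sites, variable = variable,
                 polyallelic = polyallelic, droppedEmpty = droppedEmpty))
}

## one locus alignment (character matrix, rows = sequences) -> site matrix
recodeLocus <- function(mat, population, mode) {
  nsite <- ncol(mat)
  rows <- matrix(0L, nsite, 4)
  keep <- logical(nsite)
  variable <- 0L; poly <- 0L; dropped <- 0L
  for (s in seq_len(nsite)) {
    r <- recodeBiallelic(mat[, s], population, mode)
    if (r$status == "removed") {
      if (r$reason == "polyallelic") poly <- poly + 1L else dropped <- dropped + 1L
      next
    }
    if (r$polyallelic) poly <- poly + 1L
    cn <- canonicalizeSite(r$n1, r$n2, r$r1, r$r2)
    rows[s, ] <- cn
    keep[s] <- TRUE
    if (cn[3] + cn[4] > 0) variable <- variable + 1L
  }
  m <- rows[keep, , drop = FALSE]
  colnames(m) <- c("n1", "n2", "r1", "r2")
  list(sites = m, variable = variable, polyallelic = poly, dropped = dropped)
}

readLocusFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("empty alignment: ", path)
  if (length(unique(Biostrings::width(x))) != 1)
    stop("sequences in ", path, " differ in length")
  m <- as.matrix(x)
  rownames(m) <- names(x)
  m
}

parseNexusCharsets <- function(path) {
  txt <- tolower(paste(readLines(path, warn = FALSE), collapse = "\n"))
  hits <- regmatches(txt, gregexpr("charset[^;]*;", txt))[[1]]
  out <- list()
  for (h in hits) {
    body <- sub(";$", "", sub("^charset\\s+", "", h))
    nm <- trimws(sub("=.*$", "", body))
    rng <- trimws(sub("^[^=]*=", "", body))
    ab <- as.integer(strsplit(rng, "-", fixed = TRUE)[[1]])
    out[[nm]] <- seq.int(ab[1], ab[2])
  }
  out
}

readNexusLoci <- function(path) {
  dat <- ape::read.nexus.data(path)
  m <- toupper(do.call(rbind, lapply(dat, function(x) as.character(x))))
  rownames(m) <- names(dat)
  sets <- parseNexusCharsets(path)
  if (!length(sets)) sets <- list(locus1 = seq_len(ncol(m)))
  lapply(sets, function(idx) m[, idx, drop = FALSE])
}

#' Read one comparison's multilocus alignment
#'
#' Accepts either a directory of per-locus FASTA files (one file per
#' locus; sequence identifiers must match the population map exactly) or a
#' NEXUS file whose `charset` statements delimit loci.  Sites are recoded
#' to biallelic characters and compressed into a weighted pattern table.
#' Sequences that are missing from a locus simply do not contribute gene
#' copies there; sites missing in both populations are dropped (counted in
#' `droppedEmpty`); sites missing in one population are retained.
#'
#' @param source directory of FASTA files or a NEXUS file path.
#' @param popMap a [PopulationMap-class] object.
#' @param mode polyallelic-site handling, "remove" or "recode".
#' @return a [ComparisonData-class] object.
#' @export
readComparison <- function(source, popMap, mode = c("remove", "recode")) {
  mode <- match.arg(mode)
  stopifnot(is(popMap, "PopulationMap"))
  if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(fa|fas|fasta)$",
                             full.names = TRUE))
    if (!length(files)) stop("no FASTA files found in ", source)
    mats <- lapply(files, readLocusFasta)
    names(mats) <- sub("\\.[^.]*$", "", basename(files))
  } else if (file.exists(source)) {
    mats <- readNexusLoci(source)
  } else stop("alignment source not found: ", source)

  ids <- names(popMap@assignment)
  loci <- vector("list", length(mats))
  variable <- 0L; poly <- 0L; dropped <- 0L
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    unknown <- setdiff(rownames(m), ids)
    if (length(unknown))
      stop("sequence identifier(s) not in population map: ",
           paste(unknown, collapse = ", "))
    pops <- factor(popMap@assignment[rownames(m)],
                   levels = popMap@populations)
    r <- recodeLocus(m, pops, mode)
    loci[[i]] <- r$sites
    attr(loci[[i]], "locusName") <- names(mats)[i]
    variable <- variable + r$variable
    poly <- poly + r$polyallelic
    dropped <- dropped + r$dropped
  }
  newComparisonData(popMap@label, popMap@populations, popMap@assignment,
                    loci, variable, poly, dropped)
}

#' Summarise a dataset
#'
#' Returns the per-comparison counts reported in dataset summary tables:
#' loci, retained sites, variable sites, polyallelic sites and the maximum
#' per-population gene-copy counts.
#'
#' @param data a [ComparisonData-class] object.
#' @return a one-row data.frame.
#' @export
summarizeDataset <- function(data) {
  stopifnot(is(data, "ComparisonData"))
  n1 <- if (nrow(data@patterns)) max(data@patterns$n1) else 0L
  n2 <- if (nrow(data@patterns)) max(data@patterns$n2) else 0L
  data.frame(label = data@label,
             population1 = data@populations[1],
             population2 = data@populations[2],
             copies1 = n1, copies2 = n2,
             loci = unname(data@counts["loci"]),
             sites = unname(data@counts["sites"]),
             variable = unname(data@counts["variable"]),
             polyallelic = unname(data@counts["polyallelic"]),
             stringsAsFactors = FALSE)
}

#' Write dataset summaries as tab-separated text
#'
#' @param datasets list of [ComparisonData-class] objects.
#' @param path output TSV path.
#' @return the summary data.frame, invisibly.
#' @export
writeDatasetSummary <- function(datasets, path) {
  df <- do.call(rbind, lapply(datasets, summarizeDataset))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a comparison back to per-locus FASTA
#'
#' Emits one FASTA file per locus; binary state 0 is written as `A`,
#' state 1 as `T`, missing copies as `N`.  Because pattern tables are kept
#' in a canonical orientation, re-reading the written files reproduces the
#' pattern table exactly.
#'
#' @param data a [ComparisonData-class] object.
#' @param dir output directory (created if needed).
#' @return invisibly, a [PopulationMap-class] matching the written files.
#' @export
writeComparison <- function(data, dir) {
  stopifnot(is(data, "ComparisonData"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nmax1 <- max(1L, vapply(data@loci, function(l) if (nrow(l)) max(l[, "n1"]) else 0L, 0))
  nmax2 <- max(1L, vapply(data@loci, function(l) if (nrow(l)) max(l[, "n2"]) else 0L, 0))
  ids1 <- sprintf("%s_%s_%02d", data@label, data@populations[1], seq_len(nmax1))
  ids2 <- sprintf("%s_%s_%02d", data@label, data@populations[2], seq_len(nmax2))
  for (i in seq_along(data@loci)) {
    l <- data@loci[[i]]
    seqs <- matrix("N", nmax1 + nmax2, max(1L, nrow(l)))
    for (s in seq_len(nrow(l))) {
      n1 <- l[s, "n1"]; n2 <- l[s, "n2"]; r1 <- l[s, "r1"]; r2 <- l[s, "r2"]
      col <- rep("N", nmax1 + nmax2)
      if (n1 > 0) col[seq_len(n1)] <- c(rep("A", n1 - r1), rep("T", r1))
      if (n2 > 0) col[nmax1 + seq_len(n2)] <- c(rep("A", n2 - r2), rep("T", r2))
      seqs[, s] <- col
    }
    ss <- Biostrings::DNAStringSet(apply(seqs, 1, paste, collapse = ""))
    names(ss) <- c(ids1, ids2)
    Biostrings::writeXStringSet(
      ss, file.path(dir, sprintf("locus%04d.fasta", i)))
  }
  invisible(populationMap(data@label, data@populations,
                          structure(rep(data@populations, c(nmax1, nmax2)),
                                    names = c(ids1, ids2))))
}
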