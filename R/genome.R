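#' Define a T-cell receptor locus
#'
#' A TCR locus is a named half-open genomic interval inside which
#' RAG-mediated V(D)J rearrangement physiologically deletes DNA in
#' T-lineage cells. Coordinates are 0-based, half-open (BED convention).
#'
#' @param name Locus name, one of `"TCRG"`, `"TCRD"`, `"TCRB"`, `"TCRA"`.
#' @param chrom Chromosome name the locus lies on.
#' @param start,end Integer bounds of the half-open interval `[start, end)`.
#' @return An object of class `tcr_locus`.
#' @export
#' @examples
#' tcr_locus("TCRG", "chr1", 2e7, 2.03e7)
tcr_locus <- function(name, chrom, start, end) {
  name <- match.arg(name, c("TCRG", "TCRD", "TCRB", "TCRA"))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start < end)) stop("tcr_locus: start must be < end")
  structure(list(name = name, chrom = as.character(chrom),
                 start = start, end = end),
            class = "tcr_locus")
}

#' Build a genome model
#'
#' Holds the coordinate space the simulator and the calling pipeline share:
#' an ordered set of chromosomes with lengths, plus the configurable TCR
#' locus intervals used for annotation of candidate calls.
#'
#' @param chromosomes Data frame with columns `name` and `length` (bp),
#'   one row per chromosome, in genome order.
#' @param tcr_loci List of [tcr_locus()] objects. Loci must lie within
#'   their chromosome and must not overlap one another.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, tcr_loci = list()) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("genome_model: duplicated chromosome names")
  if (any(chromosomes$length <= 0))
    stop("genome_model: chromosome lengths must be > 0")
  for (loc in tcr_loci) {
    if (!inherits(loc, "tcr_locus")) stop("tcr_loci must be tcr_locus objects")
    i <- match(loc$chrom, chromosomes$name)
    if (is.na(i)) stop("tcr locus ", loc$name, " on unknown chromosome ", loc$chrom)
    if (loc$start < 0 || loc$end > chromosomes$length[i])
      stop("tcr locus ", loc$name, " outside its chromosome")
  }
  nm <- vapply(tcr_loci, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("genome_model: duplicated TCR locus names")
  if (length(tcr_loci) > 1) {
    for (i in seq_len(length(tcr_loci) - 1)) for (j in (i + 1):length(tcr_loci)) {
      a <- tcr_loci[[i]]; b <- tcr_loci[[j]]
      if (a$chrom == b$chrom && a$start < b$end && b$start < a$end)
        stop("genome_model: TCR loci ", a$name, " and ", b$name, " overlap")
    }
  }
  structure(list(chromosomes = chromosomes, tcr_loci = tcr_loci),
            class = "genome_model")
}

#' Default toy genome
#'
#' A three-autosome, 150 Mb coordinate space carrying all four TCR loci at
#' configurable positions. Desk-scale stand-in for the human genome: large
#' enough that 50-probe events at the default platform densities span
#' hundreds of kilobases, as they do on real arrays.
#'
#' @return A `genome_model`.
#' @export
default_genome <- function() {
  genome_model(
    chromosomes = data.frame(
      name = c("chr1", "chr2", "chr3"),
      length = c(60e6, 50e6, 40e6)
    ),
    tcr_loci = list(
      tcr_locus("TCRG", "chr1", 20.0e6, 20.3e6),
      tcr_locus("TCRD", "chr2", 10.0e6, 10.4e6),
      tcr_locus("TCRA", "chr2", 10.5e6, 11.1e6),
      tcr_locus("TCRB", "chr3", 18.0e6, 18.5e6)
    )
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      sum(x$chromosomes$length) / 1e6, "Mb total\n")
  for (loc in x$tcr_loci)
    cat(sprintf("  %s %s:%g-%g\n", loc$name, loc$chrom, loc$start, loc$end))
  invisible(x)
}

#' Define an array platform
#'
#' Describes one genotyping array: total marker count, the fraction of
#' markers that are SNP probes (carrying B-allele frequency information;
#' the remainder are copy-number-only probes), and the per-probe noise
#' levels of the two signal channels.
#'
#' @param name Platform identifier.
#' @param n_probes Total marker count (>= 1).
#' @param snp_fraction Fraction of markers with BAF information, in `[0, 1]`.
#' @param noise_sd Per-probe log2-ratio standard deviation (> 0).
#' @param baf_sd Per-probe BAF standard deviation (> 0).
#' @return An object of class `platform_spec`.
#' @export
platform_spec <- function(name, n_probes, snp_fraction = 0.8,
                          noise_sd = 0.21, baf_sd = 0.025) {
  stopifnot(n_probes >= 1, snp_fraction >= 0, snp_fraction <= 1,
            noise_sd > 0, baf_sd > 0)
  structure(list(name = as.character(name), n_probes = as.integer(n_probes),
                 snp_fraction = snp_fraction, noise_sd = noise_sd,
                 baf_sd = baf_sd),
            class = "platform_spec")
}

#' Default platform pair
#'
#' Two platforms of differing marker density in the 2.67M : 4.3M ratio of
#' the high-resolution arrays the pipeline is designed around, scaled down
#' to desk size. `noise_sd = 0.21` puts the expected MAPD at ~0.20 (below
#' the 0.25 gate) and `baf_sd = 0.025` keeps the genotype-cluster separation
#' score near 20 even in samples whose true CNVs inflate the heterozygous
#' cluster (above the 15 gate), so default samples pass QC.
#'
#' @param scale Multiplier applied to both probe counts (default 1).
#' @return List of two `platform_spec` objects named `arrayA`, `arrayB`.
#' @export
default_platforms <- function(scale = 1) {
  list(
    arrayA = platform_spec("arrayA", n_probes = round(62000 * scale),
                           snp_fraction = 0.75, noise_sd = 0.21, baf_sd = 0.025),
    arrayB = platform_spec("arrayB", n_probes = round(100000 * scale),
                           snp_fraction = 0.85, noise_sd = 0.21, baf_sd = 0.025)
  )
}
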