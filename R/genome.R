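# Genome reference tables: chromosome lengths + centromere intervals.

#' Haploid genome length used for percent-of-genome-changed scores
#'
#' Total length in bases of the GRCh37.p13 haploid genome, the denominator of
#' both PGC variants.
#'
#' @export
GRCH37_HAPLOID_LENGTH <- 3234834689

# UCSC hg19 chromInfo lengths and gap-track centromere intervals.
.grch37_table <- function() {
  tibble::tribble(
    ~chrom,  ~length,    ~cen_start, ~cen_end,
    "chr1",  249250621L, 121535434L, 124535434L,
    "chr2",  243199373L,  92326171L,  95326171L,
    "chr3",  198022430L,  90504854L,  93504854L,
    "chr4",  191154276L,  49660117L,  52660117L,
    "chr5",  180915260L,  46405641L,  49405641L,
    "chr6",  171115067L,  58830166L,  61830166L,
    "chr7",  159138663L,  58054331L,  61054331L,
    "chr8",  146364022L,  43838887L,  46838887L,
    "chr9",  141213431L,  47367679L,  50367679L,
    "chr10", 135534747L,  39254935L,  42254935L,
    "chr11", 135006516L,  51644205L,  54644205L,
    "chr12", 133851895L,  34856694L,  37856694L,
    "chr13", 115169878L,  16000000L,  19000000L,
    "chr14", 107349540L,  16000000L,  19000000L,
    "chr15", 102531392L,  17000000L,  20000000L,
    "chr16",  90354753L,  35335801L,  38335801L,
    "chr17",  81195210L,  22263006L,  25263006L,
    "chr18",  78077248L,  15460898L,  18460898L,
    "chr19",  59128983L,  24681782L,  27681782L,
    "chr20",  63025520L,  26369569L,  29369569L,
    "chr21",  48129895L,  11288129L,  14288129L,
    "chr22",  51304566L,  13000000L,  16000000L,
    "chrX",  155270560L,  58632012L,  61632012L,
    "chrY",   59373566L,  10104553L,  13104553L
  )
}

#' Build a genome reference
#'
#' A genome reference is a tibble with one row per chromosome (columns
#' `chrom`, `length`, `cen_start`, `cen_end`) plus two attributes:
#' `haploid_length` (PGC denominator) and `sex_chromosomes` (chromosome
#' names excluded from all scar scoring).
#'
#' @param table tibble with columns `chrom`, `length`, `cen_start`, `cen_end`.
#' @param haploid_length haploid genome length in bases used as the PGC
#'   denominator.
#' @param sex_chromosomes character vector of chromosome names excluded from
#'   scoring.
#' @return a `genome_reference` tibble.
#' @export
genome_reference <- function(table,
                             haploid_length = GRCH37_HAPLOID_LENGTH,
                             sex_chromosomes = c("chrX", "chrY")) {
  table <- tibble::as_tibble(table)
  required <- c("chrom", "length", "cen_start", "cen_end")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("genome reference is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(table$chrom)) abort("duplicate chromosome in genome reference")
  if (!is.numeric(haploid_length) || length(haploid_length) != 1 ||
      !is.finite(haploid_length) || haploid_length <= 0) {
    abort("haploid_length must be a single positive number")
  }
  bad <- table$cen_start < 1 | table$cen_end > table$length |
    table$cen_end < table$cen_start | table$length <= 0
  if (any(bad)) {
    abort(paste0("centromere interval outside [1, length] for: ",
                 paste(table$chrom[bad], collapse = ", ")))
  }
  structure(table,
            haploid_length = as.numeric(haploid_length),
            sex_chromosomes = sex_chromosomes,
            class = c("genome_reference", class(table)))
}

#' GRCh37 genome reference (built in)
#'
#' Chromosome lengths and centromere intervals for chr1-22, X and Y on
#' GRCh37/hg19, with the PGC denominator 3,234,834,689 bp.
#'
#' @inheritParams genome_reference
#' @return a `genome_reference` tibble covering chr1-22, chrX, chrY.
#' @examples
#' ref <- grch37_reference()
#' @export
grch37_reference <- function(sex_chromosomes = c("chrX", "chrY")) {
  genome_reference(.grch37_table(),
                   haploid_length = GRCH37_HAPLOID_LENGTH,
                   sex_chromosomes = sex_chromosomes)
}

#' Read a genome reference from a TSV file
#'
#' Expects columns `chrom`, `length`, `cen_start`, `cen_end`.
#'
#' @param path file path.
#' @inheritParams genome_reference
#' @return a `genome_reference` tibble.
#' @export
read_genome_reference <- function(path,
                                  haploid_length = GRCH37_HAPLOID_LENGTH,
                                  sex_chromosomes = c("chrX", "chrY")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genome_reference(tab, haploid_length = haploid_length,
                   sex_chromosomes = sex_chromosomes)
}

# Autosomes (scored chromosomes) of a reference.
autosomes <- function(ref) {
  setdiff(ref$chrom, attr(ref, "sex_chromosomes"))
}

ref_lookup <- function(ref, chrom, what) {
  i <- match(chrom, ref$chrom)
  ref[[what]][i]
}
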