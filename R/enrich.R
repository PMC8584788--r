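# Classic (unweighted) preranked gene-set enrichment with a gene-label
# permutation null, nominal p and family-wise error rate.

#' Build the signed 1/p preranked gene list
#'
#' The ranking metric is `sign(log2fc) * 1 / max(p_value, p_floor)`: strongly
#' significant upregulated genes rank at the top, strongly significant
#' downregulated genes at the bottom. Ties are broken by gene id.
#'
#' @param table data frame with columns `gene`, `log2fc`, `p_value` (an `fdr`
#'   column, if present, is carried along).
#' @param p_floor cap applied to p-values to keep the metric finite.
#' @return tibble with `gene`, `metric`, ordered by decreasing metric.
#' @export
rank_genes <- function(table, p_floor = 1e-300) {
  table <- tibble::as_tibble(table)
  dup <- duplicated(table$gene)
  if (any(dup)) abort(paste0("duplicate gene: ", table$gene[dup][1]))
  drop <- is.na(table$p_value)
  if (any(drop)) {
    warn(sprintf("dropping %d record(s) with missing p-value", sum(drop)))
    table <- table[!drop, , drop = FALSE]
  }
  if (any(table$p_value < 0 | table$p_value > 1)) abort("p-values must lie in [0, 1]")
  metric <- sign(table$log2fc) * 1 / pmax(table$p_value, p_floor)
  out <- tibble(gene = table$gene, metric = metric)
  out[order(-out$metric, out$gene), , drop = FALSE]
}

# Signed maximal running-sum deviation from the sorted hit positions of a set
# of size nh in a list of length n: hits step +1/nh, misses -1/(n - nh).
# Candidate extrema occur just before and at each hit; ordering the candidate
# pairs by hit position reproduces the first-occurrence tie-break of a full
# running-sum scan.
es_from_positions <- function(pos, n) {
  nh <- length(pos)
  pos <- sort(pos)
  i <- seq_len(nh)
  top <- i / nh - (pos - i) / (n - nh)
  bottom <- (i - 1) / nh - (pos - i) / (n - nh)
  vals <- as.vector(rbind(bottom, top))
  vals[which.max(abs(vals))]
}

#' Classic enrichment score of one gene set
#'
#' Unweighted running sum over the ranked list: `+1/Nh` at member genes,
#' `-1/(N - Nh)` elsewhere; the score is the signed maximal deviation from
#' zero, in `[-1, 1]`.
#'
#' @param ranked a [rank_genes()] tibble (only the gene order is used).
#' @param set character vector of member genes.
#' @return the enrichment score (numeric scalar).
#' @export
enrichment_score <- function(ranked, set) {
  genes <- ranked$gene
  pos <- which(genes %in% set)
  if (length(pos) == 0) abort("gene set has no overlap with the ranked list")
  if (length(pos) == length(genes)) abort("gene set covers the whole ranked list")
  es_from_positions(pos, length(genes))
}

#' Preranked enrichment over a gene-set collection
#'
#' Size-filters the sets against the ranked universe, computes each classic
#' enrichment score, and builds the null by permuting the gene labels of the
#' ranked list `n_perm` times (one permutation shared by all sets per
#' iteration, so the family-wise max statistic is coherent). For each set,
#' `nominal_p = (1 + #{same-sign |ES_null| >= |ES|}) / (n_perm + 1)`, and
#' `fwer_p` uses the per-permutation maximum of same-sign |ES| over all sets,
#' computed separately for the positive-score and negative-score families.
#' `fdr_q` is a Benjamini-Hochberg adjustment of the nominal p within each
#' family. With `normalize = FALSE` (the "no normalization" mode) the NES
#' equals the ES; with `normalize = TRUE` the ES is divided by the mean
#' same-sign null |ES| of that set.
#'
#' @param ranked a [rank_genes()] tibble.
#' @param sets a named list of character vectors, or a [read_gmt()] tibble.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked universe (defaults 15 and 500).
#' @param normalize divide ES by the mean same-sign null |ES|?
#' @return tibble with `name`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`,
#'   `fwer_p`, ordered by decreasing ES within each family.
#' @export
enrich <- function(ranked, sets, n_perm = 1000, seed = 1,
                   min_size = 15, max_size = 500, normalize = FALSE) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (is.data.frame(sets)) sets <- setNames(sets$genes, sets$name)
  if (is.null(names(sets)) || any(names(sets) == "")) abort("gene sets must be named")
  genes <- ranked$gene
  n <- length(genes)
  positions <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(positions)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  dropped <- names(sets)[!keep]
  if (length(dropped) > 0) {
    inform(paste0("excluded by size filter: ", paste(dropped, collapse = ", ")))
  }
  if (!any(keep)) abort("no gene set survives the size filters")
  positions <- positions[keep]
  sizes <- sizes[keep]
  set_names <- names(sets)[keep]
  m <- length(positions)

  es <- vapply(positions, es_from_positions, numeric(1), n = n)

  set.seed(seed)
  null_es <- matrix(0, nrow = n_perm, ncol = m)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n)
    for (j in seq_len(m)) {
      null_es[p, j] <- es_from_positions(perm[positions[[j]]], n)
    }
  }

  same_sign_exceed <- vapply(seq_len(m), function(j) {
    nj <- null_es[, j]
    sum(sign(nj) == sign(es[j]) & abs(nj) >= abs(es[j]))
  }, numeric(1))
  nominal_p <- (1 + same_sign_exceed) / (n_perm + 1)

  max_pos <- apply(null_es, 1, function(r) if (any(r > 0)) max(r[r > 0]) else 0)
  max_neg <- apply(null_es, 1, function(r) if (any(r < 0)) max(abs(r[r < 0])) else 0)
  fwer_p <- vapply(seq_len(m), function(j) {
    fam_max <- if (es[j] >= 0) max_pos else max_neg
    (1 + sum(fam_max >= abs(es[j]))) / (n_perm + 1)
  }, numeric(1))

  if (normalize) {
    nes <- vapply(seq_len(m), function(j) {
      nj <- null_es[, j]
      denom <- mean(abs(nj[sign(nj) == sign(es[j])]))
      if (!is.finite(denom) || denom == 0) return(es[j])
      es[j] / denom
    }, numeric(1))
  } else {
    nes <- es
  }

  out <- tibble(name = set_names, size = as.integer(sizes), es = es, nes = nes,
                nominal_p = nominal_p, fwer_p = fwer_p)
  out$fdr_q <- NA_real_
  pos_fam <- out$es >= 0
  out$fdr_q[pos_fam] <- p.adjust(out$nominal_p[pos_fam], method = "BH")
  out$fdr_q[!pos_fam] <- p.adjust(out$nominal_p[!pos_fam], method = "BH")
  out <- out[, c("name", "size", "es", "nes", "nominal_p", "fdr_q", "fwer_p")]
  out[order(-sign(out$es), -abs(out$es)), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @param universe optional gene universe; when given, members are
#'   intersected with it and the effective size recorded.
#' @return tibble with `name`, `description`, `genes` (list column), `size`
#'   and, when a universe is given, `size_in_universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d: need name, description and >= 1 gene", bad[1]))
  }
  out <- tibble(
    name = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
  if (anyDuplicated(out$name)) abort("duplicate gene-set name in GMT")
  if (!is.null(universe)) {
    out$genes <- lapply(out$genes, intersect, y = universe)
    out$size_in_universe <- lengths(out$genes)
  }
  out$size <- lengths(out$genes)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors or a [read_gmt()]-style tibble.
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.data.frame(sets)) sets <- setNames(sets$genes, sets$name)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
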