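# Statistical confidence for pathway absence/presence in incomplete MAG bins.
#
# Two bespoke statistics:
#   f(0) = C(T-n, r) / C(T, r)   probability that all r pathway genes were
#                                missed by chance in a bin recovering n of an
#                                estimated T genes (hypergeometric, x = 0);
#   P    = C^k                   probability that all recovered pathway genes
#                                (on k distinct contigs) are contaminants,
#                                given bin contamination C.

#' Construct a bin-quality record
#'
#' Holds per-bin recovery and CheckM-style quality estimates. Completeness,
#' contamination and strain heterogeneity may be given as fractions or as
#' percent (values in (1, 100] are auto-scaled with a warning).
#'
#' @param bin_id Single character bin identifier.
#' @param n_recovered Number of protein-coding sequences recovered in the bin.
#' @param completeness Estimated completeness, fraction in (0, 1] or percent.
#' @param contamination Estimated contamination, fraction in [0, 1) or percent.
#' @param strain_heterogeneity Portion of contamination from closely related
#'   strains, fraction in [0, 1] or percent.
#' @return A one-row data frame of class `bin_quality` with columns
#'   `bin_id`, `n_recovered`, `completeness`, `contamination`,
#'   `strain_heterogeneity` (all quality columns as fractions).
#' @examples
#' bin_quality("JP1_191", 334, 10.63, 1.8, 0)
#' @export
bin_quality <- function(bin_id, n_recovered, completeness,
                        contamination = 0, strain_heterogeneity = 0) {
  if (!is.character(bin_id) || length(bin_id) != 1L || is.na(bin_id) || !nzchar(bin_id)) {
    ph_stop("input_error", "bin_id must be a single non-empty string")
  }
  if (!is_count(n_recovered)) {
    ph_stop("input_error", "n_recovered must be a single non-negative integer")
  }
  completeness <- normalize_fraction(completeness, "completeness")
  contamination <- normalize_fraction(contamination, "contamination")
  strain_heterogeneity <- normalize_fraction(strain_heterogeneity, "strain_heterogeneity")
  if (completeness <= 0 || completeness > 1) {
    ph_stop("invalid_quality_error", sprintf(
      "completeness must lie in (0, 1] after normalization, got %g", completeness))
  }
  if (contamination < 0 || contamination >= 1) {
    ph_stop("invalid_quality_error", sprintf(
      "contamination must lie in [0, 1) after normalization, got %g", contamination))
  }
  out <- data.frame(
    bin_id = bin_id,
    n_recovered = as.integer(n_recovered),
    completeness = completeness,
    contamination = contamination,
    strain_heterogeneity = strain_heterogeneity,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bin_quality", "data.frame")
  out
}

#' Construct a named gene set
#'
#' A pathway/marker set of size `r` whose joint absence probability is
#' assessed against bin incompleteness.
#'
#' @param set_id Single character identifier.
#' @param members Character vector of unique gene names, length >= 1.
#' @return An object of class `gene_set`: list with `set_id`, `members`,
#'   `size`.
#' @examples
#' gene_set("phototrophy", c("pufL", "pufM", "pufC", "bchX", "bchY", "bchZ"))
#' @export
gene_set <- function(set_id, members) {
  if (!is.character(set_id) || length(set_id) != 1L || !nzchar(set_id)) {
    ph_stop("input_error", "set_id must be a single non-empty string")
  }
  if (!is.character(members) || length(members) < 1L || anyNA(members)) {
    ph_stop("input_error", "members must be a non-empty character vector")
  }
  if (anyDuplicated(members)) {
    ph_stop("input_error", sprintf("duplicate gene names in set '%s'", set_id))
  }
  structure(
    list(set_id = set_id, members = members, size = length(members)),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (r = %d): %s\n", x$set_id, x$size,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Estimate total genome gene count from bin recovery and completeness
#'
#' `T = round(n / completeness)` (round-half-to-even). The estimate is never
#' smaller than the recovered count.
#'
#' @param n_recovered Number of coding sequences recovered (>= 1).
#' @param completeness Completeness fraction in (0, 1] (percent accepted).
#' @return Integer estimated total gene count `T`.
#' @examples
#' estimate_total_genes(334, 0.1063) # 3142
#' @export
estimate_total_genes <- function(n_recovered, completeness) {
  if (!is_count(n_recovered) || n_recovered < 1) {
    ph_stop("degenerate_bin_error", "n_recovered must be a positive integer")
  }
  completeness <- normalize_fraction(completeness, "completeness")
  if (length(completeness) != 1L || completeness <= 0 || completeness > 1) {
    ph_stop("invalid_quality_error",
            "completeness must be a single value in (0, 1] after normalization")
  }
  max(as.integer(round(n_recovered / completeness)), as.integer(n_recovered))
}

#' Hypergeometric probability mass function for gene recovery
#'
#' Probability of recovering exactly `x` genes of a set of size `r` when `n`
#' of `T` genes are sampled uniformly without replacement:
#' `C(n, x) * C(T - n, r - x) / C(T, r)`. Evaluated in log space so extreme
#' tails (<= 1e-300) remain representable.
#'
#' @param T_genes Total gene count in the genome.
#' @param n Number of genes recovered, `0 <= n <= T_genes`.
#' @param r Size of the gene set, `1 <= r <= T_genes`.
#' @param x Number of set members recovered, `0 <= x <= min(r, n)`.
#' @return Probability in [0, 1]; 0 when `r - x > T_genes - n`.
#' @examples
#' hypergeom_pmf(10, 5, 2, 0) # 10/45
#' @export
hypergeom_pmf <- function(T_genes, n, r, x) {
  for (v in list(T_genes = T_genes, n = n, r = r, x = x)) {
    if (!is_count(v)) ph_stop("domain_error", "all arguments must be non-negative integers")
  }
  if (n > T_genes || r > T_genes) {
    ph_stop("domain_error", "require n <= T_genes and r <= T_genes")
  }
  if (r < 1) ph_stop("domain_error", "r must be >= 1")
  if (x > min(r, n)) ph_stop("domain_error", "x must satisfy 0 <= x <= min(r, n)")
  if (r - x > T_genes - n) return(0)
  exp(lchoose(n, x) + lchoose(T_genes - n, r - x) - lchoose(T_genes, r))
}

#' Probability that a pathway is unsampled rather than absent
#'
#' Computes `f(0) = C(T - n, r) / C(T, r)` with `T` estimated from the bin's
#' recovery and completeness: the probability that all `r` set members were
#' missed by chance under uniform sampling without replacement. A bin is
#' flagged inconclusive when `f(0)` exceeds the decision threshold.
#'
#' @param bin A [bin_quality()] record (one row).
#' @param set A [gene_set()].
#' @param threshold Decision threshold for the inconclusive flag
#'   (default 0.05, the ">5%" convention).
#' @return A one-row data frame of class `absence_result` with columns
#'   `bin_id`, `gene_set_id`, `total_genes`, `prob_zero_recovered`,
#'   `flag_inconclusive`.
#' @examples
#' jp1_191 <- bin_quality("JP1_191", 334, 10.63)
#' rc6 <- gene_set("phototrophy", c("pufL", "pufM", "pufC", "bchX", "bchY", "bchZ"))
#' prob_absent(jp1_191, rc6) # f(0) ~ 0.51, flagged
#' @export
prob_absent <- function(bin, set, threshold = 0.05) {
  stopifnot(inherits(bin, "bin_quality"), nrow(bin) == 1L, inherits(set, "gene_set"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    ph_stop("input_error", "threshold must lie in [0, 1]")
  }
  T_genes <- estimate_total_genes(bin$n_recovered, bin$completeness)
  f0 <- hypergeom_pmf(T_genes, bin$n_recovered, set$size, 0)
  out <- data.frame(
    bin_id = bin$bin_id,
    gene_set_id = set$set_id,
    total_genes = T_genes,
    prob_zero_recovered = f0,
    flag_inconclusive = f0 > threshold,
    stringsAsFactors = FALSE
  )
  class(out) <- c("absence_result", "data.frame")
  out
}

#' Probability that all recovered pathway genes are contaminants
#'
#' `P = C^k` where `C` is the bin's contamination fraction and `k` the number
#' of distinct contigs carrying the recovered pathway genes. Because part of
#' `C` reflects strain-level heterogeneity rather than foreign DNA, an
#' adjusted probability using `C * (1 - strain_heterogeneity)` is reported
#' alongside the conservative raw value.
#'
#' @param bin A [bin_quality()] record (one row).
#' @param k_contigs Number of distinct contigs carrying the recovered genes.
#' @return A one-row data frame of class `false_assignment_result` with
#'   columns `bin_id`, `k_contigs`, `prob_all_contaminant`,
#'   `prob_all_contaminant_adjusted`.
#' @examples
#' cp2_42a <- bin_quality("CP2_42A", 2897, 79.44, 10.42, 16.13)
#' prob_false_assignment(cp2_42a, 6) # 0.1042^6 = 1.27999e-06
#' @export
prob_false_assignment <- function(bin, k_contigs) {
  stopifnot(inherits(bin, "bin_quality"), nrow(bin) == 1L)
  if (!is_count(k_contigs)) {
    ph_stop("input_error", "k_contigs must be a single non-negative integer")
  }
  C <- bin$contamination
  if (C >= 1) ph_stop("invalid_quality_error", "contamination must be < 1")
  C_adj <- C * (1 - bin$strain_heterogeneity)
  out <- data.frame(
    bin_id = bin$bin_id,
    k_contigs = as.integer(k_contigs),
    prob_all_contaminant = C^k_contigs,
    prob_all_contaminant_adjusted = C_adj^k_contigs,
    stringsAsFactors = FALSE
  )
  class(out) <- c("false_assignment_result", "data.frame")
  out
}

#' Batch absence report over bins and gene sets
#'
#' One [prob_absent()] row per (bin, gene set) pair, sorted by `bin_id` then
#' `gene_set_id`; deterministic.
#'
#' @param bins A `bin_quality` data frame (one or more rows, e.g. from
#'   [read_bin_quality()]), or a list of [bin_quality()] records.
#' @param sets A list of [gene_set()] objects (a single `gene_set` is
#'   accepted).
#' @param threshold Decision threshold passed to [prob_absent()].
#' @return A data frame of class `absence_report`.
#' @export
absence_report <- function(bins, sets, threshold = 0.05) {
  if (inherits(bins, "bin_quality")) {
    bins_df <- as.data.frame(bins)
  } else if (is.list(bins) && length(bins) > 0 &&
             all(vapply(bins, inherits, logical(1), "bin_quality"))) {
    bins_df <- do.call(rbind, lapply(bins, as.data.frame))
  } else {
    ph_stop("input_error", "bins must be a bin_quality table or list of bin_quality records")
  }
  if (nrow(bins_df) == 0L) ph_stop("input_error", "bins is empty")
  if (anyDuplicated(bins_df$bin_id)) {
    ph_stop("input_error", sprintf("duplicate bin_ids: %s",
      paste(unique(bins_df$bin_id[duplicated(bins_df$bin_id)]), collapse = ", ")))
  }
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (!is.list(sets) || length(sets) == 0L ||
      !all(vapply(sets, inherits, logical(1), "gene_set"))) {
    ph_stop("input_error", "sets must be a non-empty list of gene_set objects")
  }
  rows <- list()
  for (i in seq_len(nrow(bins_df))) {
    b <- bins_df[i, , drop = FALSE]
    class(b) <- c("bin_quality", "data.frame")
    for (s in sets) rows[[length(rows) + 1L]] <- prob_absent(b, s, threshold)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- out[order(out$bin_id, out$gene_set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("absence_report", "data.frame")
  out
}

#' Read a bin-quality table
#'
#' Expects a TSV with header columns `bin_id`, `n_cds`, `completeness_pct`,
#' `contamination_pct`, `strain_het_pct` (quality columns in percent).
#'
#' @param path Path to the TSV file.
#' @return A `bin_quality` data frame with quality columns as fractions.
#' @export
read_bin_quality <- function(path) {
  if (!file.exists(path)) ph_stop("input_error", sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("bin_id", "n_cds", "completeness_pct", "contamination_pct", "strain_het_pct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    ph_stop("input_error", sprintf("bin quality table lacks column(s): %s",
                                   paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    out <- data.frame(bin_id = character(0), n_recovered = integer(0),
                      completeness = numeric(0), contamination = numeric(0),
                      strain_heterogeneity = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("bin_quality", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    suppressWarnings(bin_quality(
      df$bin_id[i], df$n_cds[i],
      df$completeness_pct[i] / 100,
      df$contamination_pct[i] / 100,
      df$strain_het_pct[i] / 100
    ))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("bin_quality", "data.frame")
  out
}

#' Read gene sets from a two-column TSV
#'
#' Expects columns `set_id` and `gene_name`; one row per member.
#'
#' @param path Path to the TSV file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) ph_stop("input_error", sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_id", "gene_name") %in% names(df))) {
    ph_stop("input_error", "gene set table needs columns set_id, gene_name")
  }
  ids <- unique(df$set_id)
  stats::setNames(lapply(ids, function(id) {
    gene_set(id, df$gene_name[df$set_id == id])
  }), ids)
}

#' Write an absence report as TSV and JSON
#'
#' Probabilities are serialized in scientific notation with at least six
#' significant digits; the JSON carries the decision threshold used.
#'
#' @param report An [absence_report()] data frame.
#' @param tsv,json Output paths; either may be `NULL` to skip.
#' @return Invisibly, the report.
#' @export
write_absence_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "absence_report"))
  if (!is.null(tsv)) {
    out <- as.data.frame(report)
    out$prob_zero_recovered <- format(out$prob_zero_recovered, digits = 7, scientific = TRUE)
    utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(
      threshold = attr(report, "threshold") %||% 0.05,
      results = as.data.frame(report)
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
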