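# Loader for the bundled Chloroflexi phototrophy case study.

#' Load the bundled Chloroflexi case-study fixtures
#'
#' Returns the plain-text fixtures shipped with the package (see
#' `system.file("extdata", "MANIFEST.md", package = "photoHGT")`): bin
#' quality statistics, the marker presence/absence matrix, the organismal
#' cladogram, both encodings of the reaction-center tree, the fusion-state
#' table and the phototroph leaf set.
#'
#' @return A list of class `chloroflexi_fixtures` with elements
#'   `bin_quality` (a `bin_quality` data frame, quality columns as
#'   fractions), `metagenome_bins` (the ten bin ids, isolate excluded),
#'   `gene_sets` (named list of [gene_set()]), `marker_matrix` (character
#'   matrix with verbatim annotations), `organismal_tree`,
#'   `rc_tree_between`, `rc_tree_basal` (`phylo`), `fusion_states`
#'   (named 0/1 vector) and `phototrophs` (character).
#' @examples
#' fx <- chloroflexi_fixtures()
#' fx$bin_quality[fx$bin_quality$bin_id == "JP1_191", "completeness"] # 0.1063
#' @export
chloroflexi_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "photoHGT")
    if (!nzchar(p)) ph_stop("input_error", sprintf("fixture %s not installed", f))
    p
  }
  bq <- read_bin_quality(path("bin_quality.tsv"))
  fus <- utils::read.delim(path("fusion_states.tsv"), stringsAsFactors = FALSE)
  mm <- read_marker_matrix(path("marker_matrix.tsv"))
  structure(list(
    bin_quality = bq,
    metagenome_bins = setdiff(bq$bin_id, "Kouleothrix_aurantiaca"),
    gene_sets = read_gene_sets(path("gene_sets.tsv")),
    marker_matrix = mm,
    organismal_tree = parse_newick(readLines(path("organismal_tree.nwk"))),
    rc_tree_between = parse_newick(readLines(path("rc_tree_between.nwk"))),
    rc_tree_basal = parse_newick(readLines(path("rc_tree_basal.nwk"))),
    fusion_states = stats::setNames(as.integer(fus$fused), fus$leaf),
    phototrophs = readLines(path("phototrophs.txt"))
  ), class = "chloroflexi_fixtures")
}

#' Interpret a marker-matrix cell as presence/absence
#'
#' Cells are `-` for absent; anything else (`+`, `+ (fused)`, `nirK`, ...)
#' records presence of at least one pathway component.
#'
#' @param x Character vector of matrix cells.
#' @return Logical vector.
#' @export
marker_presence <- function(x) {
  !(trimws(x) %in% c("-", "–", ""))
}
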