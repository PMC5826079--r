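# Marker presence/absence calling from tabular homology hits.
#
# Acceptance rule: a marker is present in a bin when at least one hit is
# near-full-length (alignment strictly longer than 90% of the shortest
# isolate reference by default) AND highly significant (e-value <= 1e-20 by
# default; the significance cutoff is a *maximum* e-value). Calls supported
# only by likely-contaminant contigs are screened out.

#' Read BLAST tabular (outfmt 6) homology hits
#'
#' Standard 12 columns (qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore); an optional 13th column is read as the
#' subject sequence length. For tblastn-style searches the query is the
#' marker protein and the subject is a bin contig.
#'
#' @param path Path to the tab-separated hit file (no header).
#' @param bin_id Bin identifier to attach to every hit.
#' @param marker Optional marker name; defaults to the query id of each hit.
#' @return Data frame of class `blast_hits` with columns `query_marker`,
#'   `bin_id`, `contig_id`, `percent_identity`, `alignment_length`,
#'   `e_value`, `bit_score`, `subject_length` (NA when absent).
#' @export
read_blast_hits <- function(path, bin_id, marker = NULL) {
  if (!file.exists(path)) ph_stop("input_error", sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ph_empty_hits(bin_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad)) {
    ph_stop("parse_error", sprintf(
      "malformed hit row at line %d: %d column(s), expected >= 12", bad[1L], nf[bad[1L]]))
  }
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[`, character(1), i)))
  out <- data.frame(
    query_marker = if (is.null(marker)) vapply(fields, `[`, character(1), 1L) else marker,
    bin_id = bin_id,
    contig_id = vapply(fields, `[`, character(1), 2L),
    percent_identity = num(3L),
    alignment_length = num(4L),
    e_value = num(11L),
    bit_score = num(12L),
    subject_length = ifelse(nf >= 13L, num(13L), NA_real_),
    stringsAsFactors = FALSE
  )
  bad_num <- which(is.na(out$alignment_length) | is.na(out$e_value))
  if (length(bad_num)) {
    ph_stop("parse_error", sprintf("non-numeric field at line %d", bad_num[1L]))
  }
  if (any(out$e_value < 0) || any(out$alignment_length < 1)) {
    ph_stop("parse_error", "e-values must be >= 0 and alignment lengths >= 1")
  }
  class(out) <- c("blast_hits", "data.frame")
  out
}

ph_empty_hits <- function(bin_id = character(0)) {
  out <- data.frame(
    query_marker = character(0), bin_id = character(0), contig_id = character(0),
    percent_identity = numeric(0), alignment_length = numeric(0),
    e_value = numeric(0), bit_score = numeric(0), subject_length = numeric(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("blast_hits", "data.frame")
  out
}

#' Construct a marker reference set
#'
#' The lengths of the marker protein in isolate genomes; the shortest one
#' anchors the full-length acceptance rule.
#'
#' @param marker Marker name.
#' @param reference_lengths Numeric vector of residue counts, all `>= 1`.
#' @return Object of class `reference_set`.
#' @export
reference_set <- function(marker, reference_lengths) {
  if (!is.character(marker) || length(marker) != 1L || !nzchar(marker)) {
    ph_stop("input_error", "marker must be a single non-empty string")
  }
  if (!is.numeric(reference_lengths) || length(reference_lengths) < 1L ||
      anyNA(reference_lengths) || any(reference_lengths < 1)) {
    ph_stop("input_error", "reference_lengths must be a non-empty vector of lengths >= 1")
  }
  structure(list(marker = marker, reference_lengths = as.numeric(reference_lengths)),
            class = "reference_set")
}

#' Read reference lengths from a TSV or protein FASTA
#'
#' A TSV needs columns `marker` and `length` (one row per isolate
#' reference); a FASTA (detected by a leading `>`) yields one reference set
#' per distinct sequence-name prefix before the first `_` unless `marker`
#' is given.
#'
#' @param path Input path.
#' @param marker Optional single marker name for FASTA input.
#' @return Named list of [reference_set()] objects.
#' @export
read_reference_lengths <- function(path, marker = NULL) {
  if (!file.exists(path)) ph_stop("input_error", sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    seqs <- ape::read.FASTA(path, type = "AA")
    lens <- lengths(seqs)
    keys <- if (is.null(marker)) sub("_.*$", "", names(seqs)) else rep(marker, length(seqs))
    return(stats::setNames(
      lapply(unique(keys), function(k) reference_set(k, unname(lens[keys == k]))),
      unique(keys)))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("marker", "length") %in% names(df))) {
    ph_stop("input_error", "reference length table needs columns marker, length")
  }
  stats::setNames(
    lapply(unique(df$marker), function(k) reference_set(k, df$length[df$marker == k])),
    unique(df$marker))
}

#' Call marker presence/absence from homology hits
#'
#' Present iff at least one hit satisfies both acceptance criteria:
#' `alignment_length > min_length_fraction * min(reference_lengths)`
#' (strict inequality) and `e_value <= max_evalue`. An empty hit list gives
#' an absent call, not an error.
#'
#' @param hits A `blast_hits` data frame (possibly zero rows) for one bin.
#' @param refs A [reference_set()] for the marker being called.
#' @param min_length_fraction Full-length rule fraction (default 0.9).
#' @param max_evalue Maximum accepted e-value (default 1e-20).
#' @param bin_id Bin id for the call; defaults to the one in `hits`.
#' @param length_basis `"alignment"` (default) measures the rule on the
#'   alignment span; `"subject"` measures it on the hit ORF length
#'   (requires the 13-column hit format).
#' @return Object of class `marker_call`: list with `bin_id`, `marker`,
#'   `status` (`present`/`absent`), `supporting_contigs` (deduplicated,
#'   sorted).
#' @export
call_marker <- function(hits, refs, min_length_fraction = 0.9,
                        max_evalue = 1e-20, bin_id = NULL,
                        length_basis = c("alignment", "subject")) {
  stopifnot(inherits(refs, "reference_set"))
  length_basis <- match.arg(length_basis)
  if (!is.numeric(min_length_fraction) || min_length_fraction < 0 || min_length_fraction > 1) {
    ph_stop("input_error", "min_length_fraction must lie in [0, 1]")
  }
  if (!is.numeric(max_evalue) || max_evalue < 0) {
    ph_stop("input_error", "max_evalue must be >= 0")
  }
  if (is.null(hits)) hits <- ph_empty_hits()
  if (!is.data.frame(hits)) ph_stop("input_error", "hits must be a data frame")
  if (is.null(bin_id)) {
    bin_id <- if (nrow(hits)) hits$bin_id[1L] else NA_character_
  }
  min_ref <- min(refs$reference_lengths)
  if (nrow(hits) == 0L) {
    return(ph_marker_call(bin_id, refs$marker, "absent", character(0)))
  }
  len <- if (length_basis == "alignment") hits$alignment_length else hits$subject_length
  if (length_basis == "subject" && anyNA(len)) {
    ph_stop("input_error", "subject lengths unavailable; use 13-column hits or length_basis='alignment'")
  }
  qual <- len > min_length_fraction * min_ref & hits$e_value <= max_evalue
  if (any(qual)) {
    ph_marker_call(bin_id, refs$marker, "present",
                   sort(unique(hits$contig_id[qual])))
  } else {
    ph_marker_call(bin_id, refs$marker, "absent", character(0))
  }
}

ph_marker_call <- function(bin_id, marker, status, contigs) {
  structure(list(bin_id = bin_id, marker = marker, status = status,
                 supporting_contigs = contigs),
            class = "marker_call")
}

#' @export
print.marker_call <- function(x, ...) {
  cat(sprintf("<marker_call> %s / %s: %s%s\n", x$bin_id, x$marker, x$status,
              if (length(x$supporting_contigs))
                sprintf(" (%s)", paste(x$supporting_contigs, collapse = ", "))
              else ""))
  invisible(x)
}

#' Screen marker calls against likely-contaminant contigs
#'
#' A present call supported only by outlier contigs becomes `screened_out`;
#' a call with at least one clean supporting contig stays present with the
#' outlier contigs removed from its support. Idempotent.
#'
#' @param calls A `marker_call` or list of them.
#' @param outlier_contigs Character vector of contig ids flagged as likely
#'   contaminants (e.g. by tetranucleotide/GC/coding-density outlier
#'   detection).
#' @return List of `marker_call` objects (a single input call is returned
#'   as a single call).
#' @export
screen_contaminant_contigs <- function(calls, outlier_contigs) {
  single <- inherits(calls, "marker_call")
  if (single) calls <- list(calls)
  if (!all(vapply(calls, inherits, logical(1), "marker_call"))) {
    ph_stop("input_error", "calls must be marker_call objects")
  }
  outlier_contigs <- as.character(outlier_contigs)
  out <- lapply(calls, function(cl) {
    if (cl$status != "present") return(cl)
    clean <- setdiff(cl$supporting_contigs, outlier_contigs)
    if (length(clean) == 0L) {
      ph_marker_call(cl$bin_id, cl$marker, "screened_out", cl$supporting_contigs)
    } else {
      ph_marker_call(cl$bin_id, cl$marker, "present", clean)
    }
  })
  if (single) out[[1L]] else out
}

#' Assemble a presence/absence marker matrix
#'
#' Dense character matrix, rows = bins, columns = markers (ordering as
#' given), entries `"+"`, `"-"` or `"screened"`. Bins/markers without a
#' call are absent (`"-"`).
#'
#' @param calls List of `marker_call` objects.
#' @param bins Character vector of row (bin) ids.
#' @param markers Character vector of column (marker) names.
#' @return Character matrix with dimnames `list(bins, markers)`.
#' @export
build_marker_matrix <- function(calls, bins, markers) {
  if (inherits(calls, "marker_call")) calls <- list(calls)
  if (!is.list(calls) || !all(vapply(calls, inherits, logical(1), "marker_call"))) {
    ph_stop("input_error", "calls must be a list of marker_call objects")
  }
  mat <- matrix("-", nrow = length(bins), ncol = length(markers),
                dimnames = list(bins, markers))
  symbol <- c(present = "+", absent = "-", screened_out = "screened")
  seen <- character(0)
  for (cl in calls) {
    if (!(cl$bin_id %in% bins) || !(cl$marker %in% markers)) {
      ph_stop("input_error", sprintf(
        "call for (%s, %s) outside the provided bin/marker lists", cl$bin_id, cl$marker))
    }
    key <- paste(cl$bin_id, cl$marker, sep = "\r")
    entry <- symbol[[cl$status]]
    if (key %in% seen && mat[cl$bin_id, cl$marker] != entry) {
      ph_stop("input_error", sprintf(
        "conflicting duplicate calls for (%s, %s)", cl$bin_id, cl$marker))
    }
    seen <- c(seen, key)
    mat[cl$bin_id, cl$marker] <- entry
  }
  mat
}

#' Write / read a marker matrix as TSV
#'
#' @param mat Character matrix from [build_marker_matrix()].
#' @param path Output (input) path.
#' @return `write_marker_matrix`: invisibly, the matrix.
#' @export
write_marker_matrix <- function(mat, path) {
  utils::write.table(cbind(bin_id = rownames(mat), as.data.frame(mat, check.names = FALSE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mat)
}

#' @rdname write_marker_matrix
#' @return `read_marker_matrix`: character matrix with bin rownames.
#' @export
read_marker_matrix <- function(path) {
  if (!file.exists(path)) ph_stop("input_error", sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"bin_id" %in% names(df)) ph_stop("input_error", "marker matrix needs a bin_id column")
  m <- as.matrix(df[, setdiff(names(df), "bin_id"), drop = FALSE])
  rownames(m) <- df$bin_id
  m
}
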