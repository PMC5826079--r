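# Marker calling from BLAST tabular hits, contaminant screening, and the
# presence/absence matrix.

refs_pufL <- reference_set("pufL", c(274, 305)) # shortest reference = 274

test_that("read_blast_hits parses outfmt 6 and reports malformed rows", {
  path <- write_hits_file(list(hit_row(len = 260), hit_row(contig = "c2", len = 120)))
  hits <- read_blast_hits(path, bin_id = "binA")
  expect_s3_class(hits, "blast_hits")
  expect_equal(nrow(hits), 2L)
  expect_identical(hits$bin_id, c("binA", "binA"))
  expect_true(all(is.na(hits$subject_length)))
  # optional 13th column = subject length
  p13 <- write_hits_file(list(hit_row(slen = 280)))
  expect_equal(read_blast_hits(p13, "binA")$subject_length, 280)
  # truncated row -> parse error naming the line
  bad <- tempfile(); writeLines(c(paste(hit_row(), collapse = "\t"), "pufL\tc9\tbroken"), bad)
  expect_error(read_blast_hits(bad, "binA"), "line 2", class = "photoHGT_parse_error")
  empty <- tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(read_blast_hits(empty, "binA")), 0L)
})

test_that("call_marker applies the full-length and e-value rules", {
  # 0.95 x shortest ref, strong e-value -> present
  h <- read_blast_hits(write_hits_file(list(hit_row(len = ceiling(0.95 * 274), evalue = 1e-30))), "b")
  expect_identical(call_marker(h, refs_pufL)$status, "present")
  # 0.80 x shortest ref fails the length rule despite e-value
  h <- read_blast_hits(write_hits_file(list(hit_row(len = round(0.80 * 274), evalue = 1e-50))), "b")
  expect_identical(call_marker(h, refs_pufL)$status, "absent")
  # full length but weak e-value fails
  h <- read_blast_hits(write_hits_file(list(hit_row(len = ceiling(0.95 * 274), evalue = 1e-10))), "b")
  expect_identical(call_marker(h, refs_pufL)$status, "absent")
  # the 90% rule is strict: exactly 0.9 x min ref is not enough
  h <- read_blast_hits(write_hits_file(list(hit_row(len = 0.9 * 280))), "b")
  expect_identical(call_marker(h, reference_set("pufL", 280))$status, "absent")
  # empty hit list is an absent call, not an error
  nohit <- tempfile(); writeLines(character(0), nohit)
  expect_identical(call_marker(read_blast_hits(nohit, "b"), refs_pufL)$status, "absent")
})

test_that("multi-contig support is unioned, deduplicated and sorted", {
  rows <- list(hit_row(contig = "c2", len = 270), hit_row(contig = "c1", len = 265),
               hit_row(contig = "c2", len = 268), hit_row(contig = "c9", len = 100))
  call <- call_marker(read_blast_hits(write_hits_file(rows), "b"), refs_pufL)
  expect_identical(call$supporting_contigs, c("c1", "c2"))
})

test_that("call_marker is monotone in both thresholds", {
  set.seed(42)
  for (i in 1:20) {
    rows <- lapply(seq_len(sample(1:5, 1)), function(j) {
      hit_row(contig = sprintf("c%d", j), len = sample(80:310, 1),
              evalue = 10^-sample(5:60, 1))
    })
    hits <- read_blast_hits(write_hits_file(rows), "b")
    strict <- call_marker(hits, refs_pufL, min_length_fraction = 0.9, max_evalue = 1e-20)
    relaxed <- call_marker(hits, refs_pufL, min_length_fraction = 0.5, max_evalue = 1e-5)
    if (strict$status == "present") expect_identical(relaxed$status, "present")
    expect_true(all(strict$supporting_contigs %in% relaxed$supporting_contigs))
  }
})

test_that("subject-length basis is available behind a flag", {
  # short alignment on a full-length ORF: absent by alignment, present by ORF
  h <- read_blast_hits(write_hits_file(list(hit_row(len = 150, slen = 270))), "b")
  expect_identical(call_marker(h, refs_pufL)$status, "absent")
  expect_identical(call_marker(h, refs_pufL, length_basis = "subject")$status, "present")
  h_no <- read_blast_hits(write_hits_file(list(hit_row(len = 150))), "b")
  expect_error(call_marker(h_no, refs_pufL, length_basis = "subject"),
               class = "photoHGT_input_error")
})

test_that("contaminant screening drops only fully-outlier-supported calls", {
  both <- ph_call <- call_marker(
    read_blast_hits(write_hits_file(list(hit_row(contig = "good", len = 270),
                                         hit_row(contig = "bad", len = 270))), "b"),
    refs_pufL)
  sole <- call_marker(read_blast_hits(write_hits_file(list(hit_row(contig = "bad", len = 270))), "b"),
                      refs_pufL)
  out <- screen_contaminant_contigs(list(both, sole), "bad")
  expect_identical(out[[1]]$status, "present")
  expect_identical(out[[1]]$supporting_contigs, "good")
  expect_identical(out[[2]]$status, "screened_out")
  # empty outlier set: identity
  expect_identical(screen_contaminant_contigs(both, character(0)), both)
  # idempotent
  twice <- screen_contaminant_contigs(screen_contaminant_contigs(list(both, sole), "bad"), "bad")
  expect_identical(twice, out)
})

test_that("marker matrix reconstructs the bundled table and conserves counts", {
  mm <- fx$marker_matrix
  bins <- rownames(mm); markers <- colnames(mm)
  calls <- list()
  for (b in bins) for (m in markers) {
    if (marker_presence(mm[b, m])) {
      calls[[length(calls) + 1L]] <- call_marker(
        read_blast_hits(write_hits_file(list(hit_row(marker = m, len = 270))), b),
        reference_set(m, 274), bin_id = b)
    }
  }
  built <- build_marker_matrix(calls, bins, markers)
  expect_identical(dim(built), c(11L, 11L))
  expect_identical(unname(built == "+"), matrix(marker_presence(mm), nrow = 11))
  # marginals: present entries equal the number of present calls
  expect_identical(sum(built == "+"), length(calls))
  expect_identical(mm["JP3_7", "Type 2 reaction center"], "+ (unfused)")
  expect_identical(mm["CP2_42A", "Type 2 reaction center"], "+ (fused)")
  # no calls -> all-absent matrix; one call -> exactly one "+"
  expect_true(all(build_marker_matrix(list(), c("a", "b"), c("m")) == "-"))
  one <- build_marker_matrix(list(calls[[1]]), bins, markers)
  expect_identical(sum(one == "+"), 1L)
  # conflicting duplicates rejected
  conflict <- ph_conflict <- calls[[1]]
  conflict$status <- "absent"; conflict$supporting_contigs <- character(0)
  expect_error(build_marker_matrix(c(calls[1], list(conflict)), bins, markers),
               class = "photoHGT_input_error")
})

test_that("reference lengths load from TSV and FASTA", {
  p <- system.file("extdata", "synthetic_reference_lengths.tsv", package = "photoHGT")
  refs <- read_reference_lengths(p)
  expect_named(refs, c("pufL", "pufM"))
  expect_equal(min(refs$pufL$reference_lengths), 274)
  fa <- tempfile(fileext = ".faa")
  writeLines(c(">pufL_ChloroflexusA", paste(rep("M", 60), collapse = ""),
               ">pufL_RoseiflexusB", paste(rep("A", 80), collapse = "")), fa)
  rfa <- read_reference_lengths(fa)
  expect_equal(sort(rfa$pufL$reference_lengths), c(60, 80))
})
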