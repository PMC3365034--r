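test_that("error-read fraction follows the linear and exact formulas", {
  f <- expected_error_read_fraction(31, 0.001)
  expect_equal(unname(f["linear_pct"]), 3.1)
  expect_equal(unname(expected_error_read_fraction(31, 0.01)["linear_pct"]), 31)
  expect_equal(unname(expected_error_read_fraction(50, 0)), c(0, 0))
  # exact formula sits just below the linear approximation
  expect_equal(unname(f["exact_pct"]), 100 * (1 - (1 - 0.001)^31))
  expect_lt(f["exact_pct"], f["linear_pct"])
  expect_error(expected_error_read_fraction(31, 1.5))
})

test_that("ploidy filter applies the strict >10% non-top-two rule per individual", {
  # exactly 10% non-top-two: retained (the rule is strictly greater-than)
  r <- ploidy_filter(matrix(c(45, 45, 10), ncol = 1))
  expect_identical(r$verdict, "retained")
  expect_equal(unname(r$fractions), 0.10)
  # 20% non-top-two: discarded
  d <- ploidy_filter(matrix(c(40, 40, 20), ncol = 1))
  expect_identical(d$verdict, "discarded")
  expect_equal(unname(d$fractions), 0.20)
  # haploid: reads beyond the single top sequence count as excess
  expect_identical(ploidy_filter(matrix(c(100, 0), ncol = 1),
                                 ploidy = 1)$verdict, "retained")
  expect_identical(ploidy_filter(matrix(c(50, 50), ncol = 1),
                                 ploidy = 1)$verdict, "discarded")
  # any single failing individual discards the whole cluster
  counts <- cbind(good = c(45, 45, 10), bad = c(40, 40, 20))
  expect_identical(ploidy_filter(counts)$verdict, "discarded")
  # individuals under the read floor are not evaluated
  sparse <- cbind(ok = c(45, 45, 10), thin = c(2, 0, 1))
  rs <- ploidy_filter(sparse, min_reads = 5)
  expect_identical(rs$verdict, "retained")
  expect_true(is.na(rs$fractions["thin"]))
  expect_error(ploidy_filter(matrix(integer(0))), "empty")
})

test_that("pseudo-reference choice is longest, then most counted, then lexical", {
  seqs <- c("ACGTACGTACGTACGTACGTACGTACGTACGTACGT",  # 36, count 5
            "ACGTACGTACGTACGTACGTACGTACGTACGTACGA",  # 36, count 9
            "ACGTACGTACGTACGTACGTACGTACGTAC")        # 30, count 100
  expect_identical(choose_pseudoreference(seqs, c(5, 9, 100)), 2L)
  expect_identical(choose_pseudoreference("ACGT", 3), 1L)
  # equal length and count: lexicographically smaller wins
  expect_identical(choose_pseudoreference(c("TTTT", "AAAA"), c(4, 4)), 2L)
})

test_that("cluster MSA places gaps only where members demand them", {
  s <- random_dna(1, 36)
  # identical members: gap-free alignment
  msa <- align_cluster(rep(s, 3), c(5, 3, 1))
  expect_identical(dim(msa), c(3L, 36L))
  expect_false(any(msa == "-"))
  # one member with a 1 bp deletion: exactly one gap column, in that row
  del <- paste(strsplit(s, "")[[1]][-20], collapse = "")
  msa2 <- align_cluster(c(s, del), c(10, 2))
  expect_identical(dim(msa2), c(2L, 36L))
  expect_identical(sum(msa2[2, ] == "-"), 1L)
  expect_identical(sum(msa2[1, ] == "-"), 0L)
  # SNP-only haplotypes: gap-free, mismatch columns at the planted sites
  snp_pos <- c(7, 19, 31)
  mut <- strsplit(s, "")[[1]]
  for (p in snp_pos) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  msa3 <- align_cluster(c(s, paste(mut, collapse = "")), c(8, 6))
  expect_false(any(msa3 == "-"))
  expect_identical(which(msa3[1, ] != msa3[2, ]), as.integer(snp_pos))
})

test_that("CIGAR strings derived from the MSA match manual construction", {
  ref <- random_dna(1, 36)
  rchars <- strsplit(ref, "")[[1]]
  # identical read
  u <- make_uniq(c(ref, ref0 = paste(rchars[-11], collapse = "")),
                 counts = matrix(c(20, 5), ncol = 1))
  sets <- build_ortholog_sets(u, list(1:2), min_reads = 1)
  set <- sets[[1]]
  expect_identical(set$verdict, "retained")
  ref_idx <- which(u$sequence == ref)
  del_idx <- which(u$sequence != ref)
  expect_identical(set$pseudo_ref, ref_idx)  # longest member
  expect_identical(set$cigar[ref_idx], "36M")
  expect_identical(set$pos[ref_idx], 1L)
  # 1 bp deletion at reference position 11
  expect_identical(set$cigar[del_idx], "10M1D25M")
  # 2 bp insertion after reference position 5 (hand-built alignment rows)
  ins_read <- paste(c(rchars[1:5], "G", "G", rchars[6:36]), collapse = "")
  ref_row <- c(rchars[1:5], "-", "-", rchars[6:36])
  read_row <- strsplit(ins_read, "")[[1]]
  got <- ddradkit:::row_to_cigar(ref_row, read_row)
  expect_identical(got$cigar, "5M2I31M")
  expect_identical(got$pos, 1L)
  # CIGAR length accounting
  cl <- cigar_lengths("10M1D25M")
  expect_identical(cl$read_len, 35L)
  expect_identical(cl$ref_span, 36L)
})

test_that("SAM emission is consistent, conservative, and valid BAM", {
  set.seed(601)
  ref <- random_dna(1, 36)
  mut <- strsplit(ref, "")[[1]]
  mut[12] <- setdiff(c("A", "C", "G", "T"), mut[12])[1]
  seqs <- c(ref, paste(mut, collapse = ""),
            paste(strsplit(ref, "")[[1]][-25], collapse = ""))
  u <- make_uniq(seqs, counts = cbind(a = c(30, 25, 2), b = c(28, 27, 1)))
  sets <- build_ortholog_sets(u, list(1:3), min_reads = 1)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "out.sam"); fa <- file.path(dir, "ref.fa")
  info <- export_sam(sets, u, sam, fa)
  # conservation: one record per observation of every aligned member
  expect_identical(info$n_records, sum(u$total))
  lines <- readLines(sam)
  recs <- lines[!startsWith(lines, "@")]
  expect_identical(length(recs), sum(u$total))
  expect_identical(sum(startsWith(lines, "@SQ")), 1L)
  expect_identical(sum(startsWith(lines, "@RG")), 2L)
  # every record reconstructs against the reference
  refseq <- readLines(fa)[2]
  for (r in recs) {
    f <- strsplit(r, "\t")[[1]]
    pos <- as.integer(f[4]); cig <- f[6]; seq <- f[10]
    cl <- cigar_lengths(cig)
    expect_identical(cl$read_len, nchar(seq))
    expect_lte(pos - 1L + cl$ref_span, nchar(refseq))
    expect_identical(nchar(f[11]), nchar(seq))  # quality length
  }
  # count-tag mode emits one record per member/sample
  info2 <- export_sam(sets, u, file.path(dir, "tag.sam"), fa, expand = FALSE)
  expect_identical(info2$n_records, sum(u$counts > 0))
  # standard toolchain accepts the output
  skip_if_not_installed("Rsamtools")
  bam <- Rsamtools::asBam(sam, file.path(dir, "out"), overwrite = TRUE)
  aln <- Rsamtools::scanBam(bam)[[1]]
  expect_identical(length(aln$pos), sum(u$total))
})

test_that("cluster report summarises verdicts and worst fractions", {
  u <- make_uniq(c("AAAAACCCCCGGGGG", "AAAAACCCCCGGGGT",
                   "TTTTTGGGGGAAAAA", "TTTTTGGGGGAAAAC", "TTTTTGGGGGAAACC"),
                 counts = matrix(c(45, 45, 40, 40, 20), ncol = 1))
  sets <- build_ortholog_sets(u, list(1:2, 3:5), min_reads = 1)
  expect_identical(vapply(sets, `[[`, character(1), "verdict"),
                   c("retained", "discarded"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_report(sets, u, path)
  rep <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(rep), 2L)
  expect_equal(rep$max_nontop_fraction, c(0, 0.20))
})
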