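test_that("cut-site finding honours recognition sites and offsets", {
  expect_identical(find_cut_sites("AAAA", "EcoRI"), integer(0))
  expect_identical(find_cut_sites("", "EcoRI"), integer(0))
  # site at index 2, EcoRI cuts G^AATTC
  expect_identical(find_cut_sites("AAGAATTCAA", "EcoRI"), 3L)
  # NlaIII cuts CATG^ (offset 4)
  expect_identical(find_cut_sites("AACATGAA", "NlaIII"), 6L)
  # N never matches inside a recognition site
  expect_identical(find_cut_sites("AAGAANTCAA", "EcoRI"), integer(0))
  # invalid enzyme definitions are rejected
  expect_error(restriction_enzyme("bad", "GAXTTC", 1))
  expect_error(restriction_enzyme("bad", "GAATTC", 7))
})

test_that("non-palindromic sites are found on both strands", {
  # AAGCTA is not its own reverse complement (TAGCTT)
  enz <- restriction_enzyme("toy", "AAGCTA", 2)
  s <- paste0("CCCC", "AAGCTA", "CCCC", "TAGCTT", "CCCC")
  # forward site at 4 -> cut 6; reverse site at 14 -> cut 14 + (6 - 2) = 18
  expect_identical(find_cut_sites(s, enz), c(6L, 18L))
  # palindromic enzymes give one cut per site despite two-strand scanning
  expect_identical(find_cut_sites("AAGAATTCAA", "EcoRI"), 3L)
})

test_that("double digest classifies and tiles fragments", {
  # one EcoRI site and one MspI site -> end, AB, end
  s <- paste0(strrep("A", 10), "GAATTC", strrep("A", 10), "CCGG",
              strrep("A", 10))
  fr <- double_digest(s, "EcoRI", "MspI")
  expect_identical(fr$frag_class, c("end", "AB", "end"))
  expect_identical(sum(fr$length), nchar(s))
  expect_identical(fr$start[1], 0L)
  expect_identical(fr$end[nrow(fr)], nchar(s))

  # zero sites -> a single terminal fragment
  fr0 <- double_digest(strrep("A", 50), "EcoRI", "MspI")
  expect_identical(nrow(fr0), 1L)
  expect_identical(fr0$frag_class, "end")

  # two adjacent EcoRI sites, no MspI -> middle fragment AA, zero AB
  s2 <- paste0(strrep("A", 8), "GAATTC", strrep("T", 8), "GAATTC",
               strrep("A", 8))
  fr2 <- double_digest(s2, "EcoRI", "MspI")
  expect_identical(fr2$frag_class, c("end", "AA", "end"))
  expect_identical(sum(fr2$frag_class == "AB"), 0L)

  expect_error(double_digest(s, "EcoRI", "EcoRI"))
})

test_that("fragments tile every random sequence and AB labelling is consistent", {
  set.seed(101)
  for (rep in 1:5) {
    s <- random_dna(1, 5000)
    fr <- double_digest(s, "NlaIII", "MluCI")
    expect_identical(sum(fr$length), nchar(s))
    expect_true(all(fr$length > 0))
    is_ab <- fr$left_enzyme != fr$right_enzyme &
      fr$left_enzyme != "chromosome-end" & fr$right_enzyme != "chromosome-end"
    expect_identical(fr$frag_class == "AB", is_ab)
  }
})

test_that("digesting the reverse complement mirrors the fragment set", {
  set.seed(102)
  s <- random_dna(1, 8000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # centre-cutting palindromic enzymes mirror exactly
  eA <- restriction_enzyme("midA", "GAATTC", 3)
  eB <- restriction_enzyme("midB", "CCGG", 2)
  fr <- double_digest(s, eA, eB)
  fr_rc <- double_digest(rc, eA, eB)
  expect_identical(sort(fr$length), sort(fr_rc$length))
  expect_identical(table(fr$frag_class), table(fr_rc$frag_class))
  # off-centre REBASE offsets shift each boundary by at most the site
  # length but preserve fragment count, classes, and total length
  fr2 <- double_digest(s, "EcoRI", "MspI")
  fr2_rc <- double_digest(rc, "EcoRI", "MspI")
  expect_identical(nrow(fr2), nrow(fr2_rc))
  expect_identical(table(fr2$frag_class), table(fr2_rc$frag_class))
  expect_identical(sum(fr2$length), sum(fr2_rc$length))
  expect_true(all(abs(sort(fr2$length) - sort(fr2_rc$length)) <= 6))
})

test_that("cut positions match a brute-force regex scan on random sequences", {
  set.seed(103)
  for (rep in 1:3) {
    s <- random_dna(1, 10000)
    for (enzname in c("EcoRI", "MspI", "NlaIII")) {
      enz <- ddrad_enzymes()[[enzname]]
      hits <- gregexpr(enz$recognition, s, fixed = TRUE)[[1]]
      expected <- if (hits[1] == -1) integer(0) else
        sort(unique(as.integer(hits) - 1L + enz$cut_offset))
      expect_identical(find_cut_sites(s, enz), expected, label = enzname)
    }
  }
})

test_that("window selection is inclusive and validated", {
  fr <- data.frame(seq_id = "s", start = 0, end = 1,
                   length = c(275, 325, 274, 326, 300, 300),
                   left_enzyme = "EcoRI", right_enzyme = "MspI",
                   frag_class = c("AB", "AB", "AB", "AB", "AA", "end"))
  sel <- ab_fragments_in_window(fr, 275, 325)
  expect_identical(nrow(sel), 2L)                 # closed interval
  expect_true(all(sel$frag_class == "AB"))
  expect_identical(nrow(ab_fragments_in_window(fr, 1000, 2000)), 0L)
  expect_error(ab_fragments_in_window(fr, 325, 275))
})

test_that("length histogram counts fragments and honours class filter", {
  fr <- data.frame(length = c(100, 100, 300), frag_class = "AB")
  h <- fragment_length_histogram(fr, bin_width = 50)
  expect_identical(sum(h$counts), 3L)
  expect_identical(h$counts[1], 2L)                       # [100, 150)
  expect_identical(h$counts[which(h$breaks == 300)], 1L)  # [300, 350)
  h0 <- fragment_length_histogram(fr[0, ], 50)
  expect_identical(h0$counts, integer(0))
})

test_that("inter-site distances follow the geometric model on a random genome", {
  g <- make_genome(1e6, gc_fraction = 0.5, seed = 104)
  fr <- double_digest(g, "NlaIII", "MluCI")
  # two 4-cutters at GC 0.5: site probability 1/256 each
  expected_mean <- 1 / (2 / 256)
  expect_lt(abs(mean(fr$length) - expected_mean) / expected_mean, 0.1)
})

test_that("fragment tables round-trip through TSV", {
  s <- paste0(strrep("A", 10), "GAATTC", strrep("A", 300), "CCGG",
              strrep("A", 10))
  fr <- double_digest(s, "EcoRI", "MspI")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_table(fr, path)
  expect_identical(read_fragment_table(path), fr)
})
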