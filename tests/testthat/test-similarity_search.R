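test_that("exact dedupe keeps first occurrences and maps duplicates", {
  d <- dedupe_exact(c(a = "AAA", b = "AAA", c = "AAC"))
  expect_identical(d$seqs, c(a = "AAA", c = "AAC"))
  expect_identical(d$mapping$kept_id, "a")
  expect_identical(d$mapping$duplicate_id, "b")

  all_distinct <- c(x = "MK", y = "ML")
  expect_identical(dedupe_exact(all_distinct)$seqs, all_distinct)
})

test_that("dedupe count equals the distinct-string count on random input", {
  set.seed(31)
  for (rep in 1:20) {
    pool <- vapply(1:8, function(i) rand_protein_str(10), character(1))
    seqs <- sample(pool, 40, replace = TRUE)
    names(seqs) <- sprintf("s%02d", seq_along(seqs))
    d <- dedupe_exact(seqs)
    expect_identical(length(d$seqs), length(unique(seqs)))
    expect_identical(nrow(d$mapping), length(seqs) - length(unique(seqs)))
  }
})

test_that("Smith-Waterman matches hand values and is symmetric", {
  expect_equal(sw_align("ACD", "ACD"), 19)  # BLOSUM62 diagonal 4 + 9 + 6
  expect_equal(sw_align("A", ""), 0)
  expect_equal(sw_align("", "MKL"), 0)
  set.seed(32)
  for (rep in 1:20) {
    a <- rand_protein_str(sample(3:30, 1))
    b <- rand_protein_str(sample(3:30, 1))
    expect_equal(sw_align(a, b), sw_align(b, a))
  }
  expect_error(sw_align("ACO", "ACD"), "not in substitution matrix")
})

test_that("Smith-Waterman equals the exhaustive local-alignment oracle", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  set.seed(33)
  for (rep in 1:50) {
    a <- rand_protein_str(sample(2:6, 1))
    b <- rand_protein_str(sample(2:6, 1))
    expect_equal(sw_align(a, b, gap_open = 11, gap_extend = 1),
                 oracle_sw(a, b, B62, 11, 1))
  }
})

test_that("Smith-Waterman agrees with Biostrings pairwiseAlignment", {
  set.seed(34)
  for (rep in 1:15) {
    a <- rand_protein_str(sample(20:60, 1))
    b <- rand_protein_str(sample(20:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 12, gapExtension = 1, scoreOnly = TRUE)
    # Biostrings charges opening+extension = 13 for a length-1 gap when
    # gapOpening = 12, i.e. our gap_open = 12
    expect_equal(sw_align(a, b, gap_open = 12, gap_extend = 1),
                 max(ref, 0))
  }
})

test_that("scores never decrease when gap penalties decrease", {
  set.seed(35)
  for (rep in 1:10) {
    a <- rand_protein_str(25); b <- rand_protein_str(25)
    grid <- expand.grid(go = c(14, 11, 8, 5), ge = c(2, 1))
    sc <- mapply(function(go, ge) sw_align(a, b, gap_open = go,
                                           gap_extend = ge),
                 grid$go, grid$ge)
    for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
      if (grid$go[i] <= grid$go[j] && grid$ge[i] <= grid$ge[j]) {
        expect_gte(sc[i] + 1e-9, sc[j])
      }
    }
  }
})

test_that("top-hit assignment transfers labels from the best reference", {
  rs <- gen_reference_set(n_refs = 12, len_range = c(40, 60), seed = 36)
  q <- rs$refs[[5]]
  hit <- top_hit(q, rs$refs, rs$labels, query_id = "q5")
  expect_identical(hit$ref_id, names(rs$refs)[5])
  expect_equal(hit$score, sw_align(q, q))
  expect_identical(hit$genus, rs$labels$genus[5])
  expect_identical(hit$host_taxon, rs$labels$host_taxon[5])
})

test_that("assignment is invariant to reference order except exact ties", {
  rs <- gen_reference_set(n_refs = 10, len_range = c(40, 60), seed = 37)
  q <- rs$refs[[3]]
  set.seed(38)
  for (rep in 1:5) {
    perm <- sample(length(rs$refs))
    hit <- top_hit(q, rs$refs[perm], rs$labels)
    expect_identical(hit$ref_id, names(rs$refs)[3])
  }
})

test_that("random queries fall below the calibrated score and become unknown", {
  rs <- gen_reference_set(n_refs = 8, len_range = c(60, 90), seed = 39)
  thr <- calibrate_min_score(rs$refs, rs$refs, n_samples = 30,
                             quantile = 1, seed = 40)
  set.seed(41)
  unknowns <- vapply(1:20, function(i) {
    top_hit(rand_protein_str(70), rs$refs, rs$labels,
            min_score = thr + 1)$genus
  }, character(1))
  expect_gte(mean(unknowns == "unknown"), 0.95)
})

test_that("planted family members and mosaics recover their source", {
  rs <- gen_reference_set(n_refs = 10, len_range = c(80, 120),
                          n_families = 2, family_size = 3,
                          family_identity = 0.9, seed = 42)
  fam <- rs$labels[!is.na(rs$labels$family), ]
  base_refs <- rs$refs[sprintf("ref%03d", 1:10)]
  for (i in seq_len(nrow(fam))) {
    hit <- top_hit(rs$refs[[fam$ref_id[i]]], base_refs, rs$labels)
    expect_identical(hit$ref_id, fam$family[i])
  }
  # mosaic query: 80% from ref001, 20% random
  set.seed(43)
  recovered <- vapply(1:20, function(i) {
    src <- strsplit(rs$refs[["ref001"]], "")[[1]]
    n <- length(src)
    cut <- round(0.8 * n)
    q <- paste(c(src[1:cut],
                 sample(mitoscreen:::AA20, n - cut, replace = TRUE)),
               collapse = "")
    top_hit(q, base_refs, rs$labels)$ref_id
  }, character(1))
  expect_gte(mean(recovered == "ref001"), 0.95)
})

test_that("the 4-mer prefilter never loses the true top hit", {
  rs <- gen_reference_set(n_refs = 15, len_range = c(50, 80),
                          n_families = 3, family_size = 2, seed = 44)
  set.seed(45)
  for (rep in 1:10) {
    src <- strsplit(rs$refs[[sample(length(rs$refs), 1)]], "")[[1]]
    keep <- round(length(src) * 0.7)
    q <- paste(src[1:keep], collapse = "")
    plain <- top_hit(q, rs$refs, rs$labels)
    filt <- top_hit(q, rs$refs, rs$labels, prefilter = TRUE)
    expect_identical(filt$ref_id, plain$ref_id)
    expect_equal(filt$score, plain$score)
  }
})
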