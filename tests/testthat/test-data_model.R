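test_that("read_interactions parses toy files, dialects and headers", {
  f <- write_tsv_lines(c("A\tB\t1", "A\tC\t0", "B\tC\t1"))
  ds <- read_interactions(f)
  expect_s3_class(ds, "ppi_dataset")
  expect_equal(n_interactions(ds), 3)
  expect_setequal(ds$proteins, c("A", "B", "C"))
  expect_equal(ds$interactions$label, c(1L, 0L, 1L))
  expect_equal(ds$interactions$protein_a, c("A", "A", "B")) # order preserved

  # header auto-detection and word/boolean label dialects
  f2 <- write_tsv_lines(c("protein_a\tprotein_b\tlabel",
                          "A\tB\tpositive", "A\tC\tNegative", "B\tC\tTRUE",
                          "B\tD\tfalse"))
  ds2 <- read_interactions(f2)
  expect_equal(ds2$interactions$label, c(1L, 0L, 1L, 0L))
  expect_true(ds2$provenance$header)

  # custom separator, extra columns ignored
  f3 <- write_tsv_lines(c("A,B,1,extra", "A,C,0,extra"))
  expect_equal(n_interactions(read_interactions(f3, sep = ",")), 2)
})

test_that("read_interactions reports malformed rows and bad labels by line", {
  f <- write_tsv_lines(c("A\tB\t1", "A\tB"))
  expect_error(read_interactions(f), "line 2")

  f2 <- write_tsv_lines(c("protein_a\tprotein_b\tlabel",
                          "A\tB\t1", "A\tC\tmaybe"))
  expect_error(read_interactions(f2), "maybe.*line 3")

  expect_error(read_interactions(tempfile()), "no such file")
})

test_that("empty files yield an empty dataset with a warning", {
  f <- write_tsv_lines(character(0))
  expect_warning(ds <- read_interactions(f), "empty")
  expect_equal(n_interactions(ds), 0)
  expect_length(ds$proteins, 0)
})

test_that("duplicate handling: exact rejected/dedupable, conflicts fatal", {
  dup <- data.frame(protein_a = c("A", "A"), protein_b = c("B", "B"),
                    label = c(1, 1))
  expect_error(ppi_dataset(dup), "duplicate")
  ds <- ppi_dataset(dup, duplicates = "deduplicate")
  expect_equal(n_interactions(ds), 1)
  expect_equal(ds$provenance$duplicates, "deduplicate")

  conflict <- data.frame(protein_a = c("A", "A"), protein_b = c("B", "B"),
                         label = c(1, 0))
  expect_error(ppi_dataset(conflict), "conflicting")
  expect_error(ppi_dataset(conflict, duplicates = "deduplicate"), "conflicting")

  # (A,B) and (B,A) are distinct ordered pairs, not duplicates
  swapped <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "A"),
                        label = c(1, 0))
  expect_equal(n_interactions(ppi_dataset(swapped)), 2)
})

test_that("write/read interaction round trip is the identity", {
  ds <- small_world(30, 120, seed = 5)$dataset
  f <- tempfile(fileext = ".tsv")
  write_interactions(ds, f)
  back <- read_interactions(f)
  expect_identical(back$interactions, ds$interactions)
  expect_identical(back$proteins, ds$proteins)
})

test_that("read_fasta keys by first header token and rejects malformed input", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">P1 some description", "mkv", ">P2", "ACDE", "FGH"), f)
  seqs <- read_fasta(f)
  expect_equal(seqs, c(P1 = "MKV", P2 = "ACDEFGH"))

  writeLines(c(">P1", "MKV", ">P1", "ACD"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c("MKV", ">P1", "ACD"), f)
  expect_error(read_fasta(f), "FASTA")
})

test_that("ppi_summary matches hand enumeration on the toy dataset", {
  s <- ppi_summary(toy6_dataset())
  expect_equal(s$n_interactions, 6)
  expect_equal(s$n_positive, 3)
  expect_equal(s$n_proteins, 4)
  st <- s$protein_stats
  rownames(st) <- st$protein
  # hand counts: A 1+/2-, B 3+/0-, C 1+/2-, D 1+/2-
  expect_equal(st[c("A", "B", "C", "D"), "positivity"],
               c(1 / 3, 1, 1 / 3, 1 / 3))
  expect_equal(s$n_only_positive, 1)
  expect_equal(s$n_only_negative, 0)
  expect_equal(s$n_mixed, 3)
  expect_equal(s$pct_single_class, 25)

  single <- ppi_dataset(data.frame(protein_a = "A", protein_b = "B", label = 1))
  s1 <- ppi_summary(single)
  expect_equal(s1$protein_stats$positivity, c(1, 1))
  expect_equal(s1$pct_single_class, 100)

  expect_error(ppi_summary(ppi_dataset(data.frame(
    protein_a = character(0), protein_b = character(0), label = integer(0)))),
    "empty")
})

test_that("summary conservation laws hold, self-interactions count once", {
  ds <- small_world(35, 180, seed = 11)$dataset
  s <- ppi_summary(ds)
  # no self-pairs from the generator: sum n_pos = 2 * dataset positives
  expect_equal(sum(s$protein_stats$n_pos), 2 * s$n_positive)
  expect_equal(sum(s$protein_stats$n_neg), 2 * s$n_negative)
  expect_equal(s$n_only_positive + s$n_only_negative + s$n_mixed, s$n_proteins)
  expect_equal(s$pct_single_class,
               100 * (s$n_only_positive + s$n_only_negative) / s$n_proteins)

  with_self <- ppi_dataset(data.frame(protein_a = c("A", "A"),
                                      protein_b = c("A", "B"),
                                      label = c(1, 0)))
  st <- ppi_summary(with_self)$protein_stats
  expect_equal(st$n_pos[st$protein == "A"], 1L) # self-interaction counted once
  expect_equal(st$n_neg[st$protein == "A"], 1L)
})

test_that("gold-standard loader checks protein disjointness", {
  dir <- tempfile()
  dir.create(dir)
  writeLines(c("A\tB\t1", "A\tC\t0"), file.path(dir, "train.tsv"))
  writeLines(c("D\tE\t1"), file.path(dir, "validation.tsv"))
  writeLines(c("F\tG\t0"), file.path(dir, "test.tsv"))
  writeLines(c(">A", "MK", ">B", "ML", ">C", "MM", ">D", "MN",
               ">E", "MP", ">F", "MQ", ">G", "MR"),
             file.path(dir, "sequences.fasta"))
  gs <- load_gold_standard(dir)
  expect_true(gs$disjoint)
  expect_equal(n_interactions(gs$train), 2)
  expect_length(gs$sequences, 7)

  # one protein shared between train and test -> warning naming it
  writeLines(c("F\tG\t0", "A\tG\t1"), file.path(dir, "test.tsv"))
  expect_warning(gs2 <- load_gold_standard(dir), "train and test.*A")
  expect_false(gs2$disjoint)

  expect_error(load_gold_standard(tempfile()), "missing")
})
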