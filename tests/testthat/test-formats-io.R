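test_that("FASTA parsing returns records in file order with normalized residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 terminase large subunit", "MKLV", ">p2", "avfg", "hik"), f)
  recs <- read_fasta(f)
  expect_equal(recs$protein_id, c("p1", "p2"))
  expect_equal(recs$description, c("terminase large subunit", ""))
  expect_equal(recs$residues, c("MKLV", "AVFGHIK"))
})

test_that("FASTA parsing rejects duplicates, empty files and headerless input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">dup", "MK", ">dup", "LV"), f)
  expect_error(read_fasta(f), "dup")
  writeLines(character(), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c("MKLV", ">p1", "MK"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("alignment tables parse with the default column map", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\tt1\t0.8\t0.95\t0.92\t1e-10", f)
  aln <- read_alignment_table(f)
  expect_equal(aln$seq_identity, 0.8)
  expect_equal(aln$evalue, 1e-10)
  # columns 7+ absent from the file: optional fields become NA
  expect_true(is.na(aln$tm_score))
  expect_true(is.na(aln$target_name))
})

test_that("alignment tables validate fractional fields with a row index", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tt1\t0.8\t0.95\t0.92\t1e-10",
               "q2\tt2\t1.3\t0.95\t0.92\t1e-10"), f)
  expect_error(read_alignment_table(f), "row 2.*seq_identity")
})

test_that("alignment db tags are normalized and extra columns read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tt1\t0.5\t0.9\t0.9\t1e-5\t0.7\t0.8\tcapsid protein\t562\tPDB",
               "q2\tt2\t0.5\t0.9\t0.9\t1e-5\t0.7\t0.8\tname\t562\tmystery_db"), f)
  aln <- read_alignment_table(f)
  expect_equal(aln$target_db, c("PDB", "other"))
  expect_equal(aln$target_taxid, c(562L, 562L))
})

test_that("cluster TSV parsing builds a partition and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tr1", "r1\ta", "r2\tr2"), f)
  cl <- read_cluster_tsv(f)
  expect_equal(sort(unname(lengths(cl$clusters))), c(1L, 2L))
  expect_setequal(cl$clusters[["r1"]], c("a", "r1"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_tsv(cl, out)
  expect_equal(read_cluster_tsv(out)$clusters, cl$clusters)
})

test_that("cluster TSV rejects members under two representatives", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tr1", "r1\ta", "r2\tr2", "r2\ta"), f)
  expect_error(read_cluster_tsv(f), "partition")
})

test_that("empty cluster file yields an empty clustering", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f)
  cl <- read_cluster_tsv(f)
  expect_length(cl$clusters, 0L)
})

test_that("pLDDT extraction prefers CA atoms and clamps out-of-range values", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 55.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00 70.00           C",
    "ATOM      3  CA  ALA A   2       2.000   0.000   0.000  1.00 80.00           C",
    "ATOM      4  CB  ALA A   2       2.500   0.000   0.000  1.00 10.00           C",
    "ATOM      5  CA  ALA A   3       3.000   0.000   0.000  1.00 90.00           C",
    "END")
  writeLines(lines, f)
  m <- read_plddt(f)
  expect_s3_class(m, "structure_model")
  expect_equal(m$plddt, c(70, 80, 90))
  expect_equal(mean_plddt(m), 80)

  # first atom used when no CA; values above 100 clamped with a warning
  writeLines(c(
    "ATOM      1  P     U A   1       0.000   0.000   0.000  1.00120.00           P",
    "END"), f)
  expect_warning(m2 <- read_plddt(f), "clamped")
  expect_equal(m2$plddt, 100)
})

test_that("pLDDT extraction errors on files without residues", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_plddt(f))
})

test_that("GFF product extraction handles present, missing and encoded products", {
  f <- withr::local_tempfile(fileext = ".gff")
  writeLines(c(
    "##gff-version 3",
    "ph1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=g1;product=hypothetical protein",
    "ph1\tsrc\tCDS\t400\t700\t.\t+\t0\tID=g2",
    "ph1\tsrc\tgene\t1\t300\t.\t+\t.\tID=gene1",
    "ph1\tsrc\tCDS\t800\t900\t.\t+\t0\tID=g3;product=tail%20fiber protein"), f)
  pr <- read_products_from_gff(f)
  expect_equal(pr$protein_id, c("g1", "g2", "g3"))
  expect_equal(pr$product, c("hypothetical protein", "", "tail fiber protein"))
  expect_true(all(pr$source == "sequence"))
})

test_that("taxdump parsing finds the root and rejects broken trees", {
  d <- withr::local_tempdir()
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "2\t|\t1\t|\tsuperkingdom\t|",
               "3\t|\t2\t|\tgenus\t|",
               "4\t|\t3\t|\tspecies\t|"), file.path(d, "nodes.dmp"))
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
               "2\t|\teubacteria\t|\t\t|\tsynonym\t|",
               "3\t|\tMycobacterium\t|\t\t|\tscientific name\t|",
               "4\t|\tMycobacterium smegmatis\t|\t\t|\tscientific name\t|"),
             file.path(d, "names.dmp"))
  tree <- read_taxdump(file.path(d, "nodes.dmp"), file.path(d, "names.dmp"))
  expect_equal(tree$root, 1L)
  expect_equal(tree$name[match(2L, tree$taxid)], "Bacteria")
  expect_equal(tree$depth, 0:3)

  # orphan parent
  writeLines(c("1\t|\t1\t|\tno rank\t|", "2\t|\t9\t|\tgenus\t|"),
             file.path(d, "nodes.dmp"))
  expect_error(read_taxdump(file.path(d, "nodes.dmp"), file.path(d, "names.dmp")),
               "absent")
  # two self-parented roots
  writeLines(c("1\t|\t1\t|\tno rank\t|", "2\t|\t2\t|\tno rank\t|"),
             file.path(d, "nodes.dmp"))
  expect_error(read_taxdump(file.path(d, "nodes.dmp"), file.path(d, "names.dmp")),
               "root")
})
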