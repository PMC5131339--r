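test_that("PDB parsing extracts the CA trace with author numbering", {
  s <- read_structure(gpc_pdb())
  expect_s3_class(s, "ums_structure")
  expect_equal(nrow(s), 3)
  expect_equal(unique(s$chain), "A")
  expect_equal(s$position, 1:3)
  expect_equal(paste(s$wt, collapse = ""), "GPC")

  expect_warning(s2 <- read_structure(gpc_pdb(with_water = TRUE)), "HETATM")
  expect_equal(s2$wt, s$wt)
  expect_equal(nrow(s2), 3)
})

test_that("toy helix round-trips through the PDB reader", {
  s <- read_structure(make_toy_structure(10, seed = 1))
  expect_equal(nrow(s), 10)
  expect_equal(s$position, 1:10)
  expect_true(all(diff(s$position) > 0))
})

test_that("structure reader error contracts hold", {
  expect_error(read_structure("JUNK\nMORE JUNK\n"), "ATOM")
  expect_error(read_structure(gpc_pdb(), chain = "B"), "Chain 'B'")
  # insertion code in column 27 of the PRO record
  lines <- strsplit(gpc_pdb(), "\n")[[1]]
  substr(lines[2], 27, 27) <- "A"
  expect_error(read_structure(paste(lines, collapse = "\n")), "insertion")
})

test_that("non-standard residues map to parents or are skipped", {
  lines <- strsplit(gpc_pdb(), "\n")[[1]]
  lines[2] <- sub("PRO", "MSE", lines[2])
  expect_warning(s <- read_structure(paste(lines, collapse = "\n")),
                 "non-standard")
  expect_equal(paste(s$wt, collapse = ""), "GMC")

  lines[2] <- sub("MSE", "UNK", lines[2])
  expect_warning(s2 <- read_structure(paste(lines, collapse = "\n")),
                 "no standard parent")
  expect_equal(nrow(s2), 2)
})

test_that("enumeration yields 20 specs per residue in deterministic order", {
  s10 <- read_structure(make_toy_structure(10, seed = 1))
  specs10 <- enumerate_mutations(s10)
  expect_equal(nrow(specs10), 200)

  # single-residue structure: 20 specs, exactly one identity
  ala <- paste0(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C\n")
  specs1 <- enumerate_mutations(read_structure(ala))
  expect_equal(nrow(specs1), 20)
  expect_equal(sum(specs1$is_identity), 1)
  expect_equal(specs1$mut[specs1$is_identity], "A")

  # brute-force oracle: independent enumeration over the 20 codes
  s <- read_structure(gpc_pdb())
  specs <- enumerate_mutations(s)
  oracle <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(position = i, wt = c("G", "P", "C")[i],
               mut = sort(amino_acids()))
  }))
  expect_equal(nrow(specs), 60)
  expect_equal(specs$position, oracle$position)
  expect_equal(specs$wt, oracle$wt)
  expect_equal(specs$mut, oracle$mut)
  pos2 <- dplyr::filter(specs, position == 2)
  expect_true(all(pos2$wt == "P"))
  expect_equal(pos2$mut[pos2$is_identity], "P")
  expect_equal(sum(specs$is_identity), 3)
})

test_that("mutation lists serialise per dialect and round-trip", {
  spec <- tibble::tibble(chain = "A", position = 23L, wt = "P", mut = "H",
                         is_identity = FALSE)
  # independent string assembly from the fields
  expect_equal(write_mutation_list(spec, "foldx_individual"),
               paste0(paste0("P", "A", 23, "H", ";"), "\n"))
  ident <- tibble::tibble(chain = "A", position = 1L, wt = "A", mut = "A",
                          is_identity = TRUE)
  expect_equal(write_mutation_list(ident, "foldx_individual"), "AA1A;\n")

  specs <- enumerate_mutations(read_structure(make_toy_structure(10, seed = 1)))
  lines <- strsplit(write_mutation_list(specs, "foldx_individual"), "\n")[[1]]
  lines <- lines[nzchar(lines)]
  expect_length(lines, 200)
  expect_equal(anyDuplicated(lines), 0)

  # tsv round trip is the identity on key fields
  back <- read_mutation_list(write_mutation_list(specs, "tsv"), "tsv")
  expect_equal(back[c("chain", "position", "wt", "mut")],
               specs[c("chain", "position", "wt", "mut")])
  back2 <- read_mutation_list(write_mutation_list(specs, "foldx_individual"),
                              "foldx_individual")
  expect_equal(back2$position, specs$position)
  expect_equal(back2$mut, specs$mut)

  expect_error(write_mutation_list(spec, "nonsense"))
  expect_error(write_mutation_list(spec[0, ], "tsv"), "Empty")
})

test_that("ddG tables parse with sign normalisation", {
  tsv <- "chain\tposition\twt\tmut\tddg_kcal_mol\nA\t23\tP\tH\t3.20\n"
  t1 <- read_ddg_table(tsv, sign_convention = "destabilizing_positive")
  expect_equal(t1$ddg, 3.20)
  # a destabilizing mutation written as -3.20 under the negative convention
  tsv_neg <- "chain\tposition\twt\tmut\tddg_kcal_mol\nA\t23\tP\tH\t-3.20\n"
  t2 <- read_ddg_table(tsv_neg, sign_convention = "destabilizing_negative")
  expect_equal(t2$ddg, 3.20)

  # idempotence: ingesting an already-normalised table changes no value
  s <- read_structure(gpc_pdb())
  syn <- make_synthetic_ddg(s, seed = 3)$ddg
  round1 <- read_ddg_table(write_ddg_table(syn), "tsv",
                           "destabilizing_positive")
  round2 <- read_ddg_table(write_ddg_table(round1), "tsv",
                           "destabilizing_positive")
  expect_equal(round2$ddg, round1$ddg)
  expect_equal(round1$ddg, syn$ddg)

  # synthetic table covers exactly the enumerated mutations
  expect_equal(nrow(round1), nrow(enumerate_mutations(s)))
})

test_that("ddG table error contracts name the offending key or line", {
  dup <- paste0("chain\tposition\twt\tmut\tddg_kcal_mol\n",
                "A\t23\tP\tH\t3.2\nA\t23\tP\tH\t1.1\n")
  expect_error(read_ddg_table(dup), "A:23:H")
  bad <- "chain\tposition\twt\tmut\tddg_kcal_mol\nA\t23\tP\tH\tabc\n"
  expect_error(read_ddg_table(bad), "line 2")
  expect_error(read_ddg_table("   "), "Empty")
})

test_that("FoldX difference output pairs energies with the mutation list", {
  mlist <- "PA23H;\nGA24A;\n"
  dif <- paste0("FoldX difference file\n",
                "Pdb\ttotal energy\tBackbone Hbond\n",
                "mut_1.pdb\t2.50\t0.1\n",
                "mut_2.pdb\t-0.75\t0.0\n")
  tbl <- read_ddg_table(dif, dialect = "foldx_dif", mutation_list = mlist)
  expect_equal(tbl$ddg, c(2.50, -0.75))
  expect_equal(tbl$position, c(23L, 24L))
  expect_equal(tbl$mut, c("H", "A"))
  short <- sub("mut_2.pdb\t-0.75\t0.0\n", "", dif, fixed = TRUE)
  expect_error(read_ddg_table(short, dialect = "foldx_dif",
                              mutation_list = mlist), "2 specs")
})
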