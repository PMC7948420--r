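registry <- modification_registry()

test_that("monoisotopic mass matches the elemental-composition oracle", {
  expect_equal(monoisotopic_mass(peptidoform("G")), 57.02146 + 18.01056,
               tolerance = 1e-4)
  set.seed(42)
  aa <- names(amino_acid_masses())
  for (k in 1:20) {
    seq <- paste(sample(aa, sample(3:20, 1), replace = TRUE), collapse = "")
    expect_equal(monoisotopic_mass(peptidoform(seq)),
                 oracle_peptide_mass(seq), tolerance = 1e-3)
  }
  expect_equal(monoisotopic_mass(peptidoform("KSAPSTGGVKKPHR")),
               1448.8212, tolerance = 1e-3)
  pf <- peptidoform("KSAPSTGGVKKPHR",
                    data.frame(position = c(1, 10, 11),
                               name = "propionyl"))
  expect_equal(monoisotopic_mass(pf), 1448.8212 + 3 * 56.02621,
               tolerance = 1e-3)
  expect_error(peptidoform("KSB"), "invalid sequence")
})

test_that("mass additivity: modification deltas add exactly", {
  set.seed(7)
  for (k in 1:10) {
    seq <- "MKSTYCKR"
    mods <- data.frame(position = c(3, 5, 7), # S, Y, K
                       name = c("phospho", "phospho", "acetyl"))
    pf <- peptidoform(seq, mods)
    delta <- monoisotopic_mass(pf) - monoisotopic_mass(peptidoform(seq))
    expect_equal(delta, sum(mod_delta(mods$name, registry)), tolerance = 1e-9)
  }
})

test_that("the four H3K36 methyl-peptidoform m/z values are reproduced", {
  pfs <- h3k36_peptidoforms(charge = 3L)
  expect_equal(round(mz(pfs$me0), 2), 539.97)
  expect_equal(round(mz(pfs$me1), 2), 544.65)
  expect_equal(round(mz(pfs$me2), 2), 530.64)
  expect_equal(round(mz(pfs$me3), 2), 535.31)
  # me0/me1 are triply, me2/me3 doubly propionylated
  n_prop <- vapply(pfs, function(p) sum(p$mods$name == "propionyl"),
                   numeric(1))
  expect_equal(unname(n_prop), c(3, 3, 2, 2))
})

test_that("m/z respects its definition and is decreasing in charge", {
  pf1 <- peptidoform("AKSAPK", charge = 1L)
  expect_equal(mz(pf1), monoisotopic_mass(pf1) + proton_mass())
  mzs <- vapply(1:5, function(z)
    mz(peptidoform("KSAPSTGGVKKPHR", charge = z)), numeric(1))
  expect_true(all(diff(mzs) < 0))
  expect_error(mz(peptidoform("AK")), "charge")
})

test_that("propionylation follows methylation-state chemistry", {
  pf0 <- propionylate("KSAPSTGGVKKPHR", list(`10` = "me0"))
  expect_equal(sum(pf0$mods$name == "propionyl"), 3)
  pf3 <- propionylate("KSAPSTGGVKKPHR", list(`10` = "me3"))
  expect_equal(sum(pf3$mods$name == "propionyl"), 2)
  expect_equal(pf3$mods$name[pf3$mods$position == 10], "trimethyl")
  pf1 <- propionylate("KSAPSTGGVKKPHR", list(`10` = "me1"))
  expect_setequal(pf1$mods$name[pf1$mods$position == 10],
                  c("methyl", "propionyl"))
  expect_equal(nrow(propionylate("ASGR")$mods), 0)
  expect_equal(propionylate("AKG", nterm = TRUE)$mods$position, c(0L, 2L))
  expect_error(propionylate("AKG", list(`1` = "me2")), "non-lysine")
  expect_error(propionylate("AKG", list(`2` = "me4")), "invalid state")
})

test_that("digestion rules reproduce manual cleavage", {
  d <- digest("AKPGKR", "trypsin")
  expect_equal(d$peptide, c("AKPGK", "R"))
  expect_equal(d$start, c(1, 6))
  expect_equal(d$end, c(5, 6))
  d2 <- digest("AKGR", "lysarginase")
  expect_equal(d2$peptide, c("A", "KG", "R"))
  expect_true("KR" %in% digest("KR", "trypsin", max_missed = 1)$peptide)
  d3 <- digest("GADGE", "aspn")
  expect_equal(d3$peptide, c("GA", "DG", "E"))
  expect_equal(digest("GADGE", "aspn", aspn_residues = "D")$peptide,
               c("GA", "DGE"))
  d4 <- digest("GFPAW", "chymotrypsin")
  expect_equal(d4$peptide, c("GFPAW"))
  expect_error(digest("AK", "pepsin"), "unknown protease")
})

test_that("zero-missed-cleavage digests tile the protein", {
  set.seed(11)
  aa <- names(amino_acid_masses())
  for (prot in replicate(5, paste(sample(aa, 60, TRUE), collapse = ""))) {
    for (enz in c("trypsin", "lysarginase", "aspn", "chymotrypsin")) {
      d <- digest(prot, enz, max_missed = 0)
      expect_equal(paste(d$peptide, collapse = ""), prot)
      expect_equal(d$start[-1], d$end[-nrow(d)] + 1)
    }
    d3 <- digest(prot, "trypsin", max_missed = 3)
    expect_true(all(d3$missed_cleavages <= 3))
    # every <=3-missed product is the concatenation of consecutive fully
    # cleaved peptides
    base <- digest(prot, "trypsin", max_missed = 0)
    expect_true(all(d3$start %in% base$start) && all(d3$end %in% base$end))
  }
})

test_that("ppm windows are symmetric, contain the center, and scale", {
  w <- ppm_window(1000, 10)
  expect_equal(unname(w), c(999.99, 1000.01))
  w2 <- ppm_window(539.97, 10)
  expect_equal(unname(diff(w2)), 539.97 * 2e-5, tolerance = 1e-12)
  expect_true(w2[1] < 539.97 && 539.97 < w2[2])
  expect_error(ppm_window(-1, 10), "invalid argument")
  expect_error(ppm_window(500, 0), "invalid argument")
})
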