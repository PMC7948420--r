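test_that("disorder calls match exhaustive per-residue counting", {
  track <- disorder_track(rep(0.9, 50))
  sites <- data.frame(position = c(3, 10, 30, 44))
  res <- disorder_context(sites, track)
  expect_equal(res$tally$pct_disordered, 100)
  expect_equal(res$tally$n_sites_disordered, 4)
  half <- disorder_track(rep(c(1, 0), each = 25))
  expect_equal(disorder_context(sites[0, , drop = FALSE],
                                half)$tally$pct_disordered, 50)
  set.seed(13)
  for (k in 1:5) {
    sc <- runif(80)
    tr <- disorder_track(sc, threshold = 0.5)
    pos <- sample(80, 12)
    out <- disorder_context(data.frame(position = pos), tr)
    expect_equal(out$sites$disordered, sc[pos] >= 0.5)
    expect_equal(out$tally$n_sites_disordered, sum(sc[pos] >= 0.5))
    expect_equal(out$tally$pct_disordered, 100 * mean(sc >= 0.5))
  }
  expect_error(disorder_context(data.frame(position = 99), track),
               "bounds error")
})

test_that("domain membership is endpoint-inclusive and tallied", {
  domains <- data.frame(protein_id = "P1", name = "SET",
                        start = 50, end = 150, class = "catalytic")
  at_start <- domain_context(data.frame(protein_id = "P1", position = 50),
                             domains)
  expect_true(at_start$sites$in_domain)
  at_end <- domain_context(data.frame(protein_id = "P1", position = 150),
                           domains)
  expect_true(at_end$sites$in_domain)
  outside <- domain_context(data.frame(protein_id = "P1", position = 151),
                            domains)
  expect_false(outside$sites$in_domain)
  # 143 sites with 15 planted in-domain reproduces a 10.5% tally
  set.seed(2)
  pos <- c(sample(50:150, 15), sample(c(1:49, 151:600), 128))
  res <- domain_context(data.frame(protein_id = "P1", position = pos), domains)
  expect_equal(round(100 * res$fraction_in_domain, 1), 10.5)
  none <- domain_context(data.frame(protein_id = "P1", position = 5),
                         domains[0, , drop = FALSE])
  expect_equal(none$fraction_in_domain, 0)
})

test_that("BED-style domain input converts to 1-based inclusive", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("protein_id\tname\tstart\tend\tclass\nP1\tSET\t49\t150\tcatalytic",
             f)
  dom <- read_domains(f, zero_based_half_open = TRUE)
  expect_equal(dom$start, 50)
  expect_equal(dom$end, 150)
})

test_that("the N-terminal charge model reproduces the five mutant charges", {
  expect_equal(net_charge(set2_nterm_window()), -7)
  expect_equal(net_charge(set2_nterm_window(c(`6` = "A", `8` = "A",
                                              `10` = "A"))), -1)
  expect_equal(net_charge(set2_nterm_window(c(`6` = "D", `8` = "D",
                                              `10` = "D"))), -4)
  for (p in c("6", "8", "10")) {
    expect_equal(net_charge(set2_nterm_window(stats::setNames("A", p))), -5)
    expect_equal(net_charge(set2_nterm_window(stats::setNames("D", p))), -6)
  }
  expect_error(set2_nterm_window(c(`3` = "A")), "invalid mutation")
  expect_error(set2_nterm_window(c(`6` = "W")), "invalid mutation")
})

test_that("charge contributions are additive over independent positions", {
  wt <- net_charge(set2_nterm_window())
  for (p in c("6", "8", "10")) {
    expect_equal(net_charge(set2_nterm_window(stats::setNames("A", p))) - wt, 2)
    expect_equal(net_charge(set2_nterm_window(stats::setNames("D", p))) - wt, 1)
  }
  double <- net_charge(set2_nterm_window(c(`6` = "A", `8` = "D")))
  expect_equal(double - wt, 3)
})

test_that("conserved-phosphosite calls cover all outcome classes", {
  a <- "MKSTPSAYR"
  al_self <- align_free_end_gaps(a, a)
  own <- data.frame(position = c(3, 6, 8))
  self <- conserved_phosphosites(own, al_self, a, partner_phospho = c(3, 6, 8))
  expect_true(all(self$conservation == "phosphosite_conserved"))
  # partner lacking the C-terminal part: site aligned to a gap
  b <- "MKSTP"
  al <- align_free_end_gaps(a, b)
  res <- conserved_phosphosites(data.frame(position = c(3, 8)), al, b,
                                partner_phospho = integer())
  expect_equal(res$conservation, c("residue_conserved", "not_aligned"))
  # planted: 6 of the conserved residues are known partner phosphosites
  set.seed(17)
  seq_a <- paste(sample(names(amino_acid_masses()), 60, TRUE), collapse = "")
  al2 <- align_free_end_gaps(seq_a, seq_a)
  sty <- which(strsplit(seq_a, "")[[1]] %in% c("S", "T", "Y"))
  sites <- data.frame(position = sty[seq_len(min(19, length(sty)))])
  partner <- sites$position[1:6]
  out <- conserved_phosphosites(sites, al2, seq_a, partner)
  expect_equal(sum(out$conservation == "phosphosite_conserved"), 6)
})
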