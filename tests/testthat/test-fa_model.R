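test_that("labels across all dialects parse to the expected descriptors", {
  cases <- list(
    list("a-C15:0",  carbons = 15, db = 0, branch = "anteiso"),
    list("aC15:0",   carbons = 15, db = 0, branch = "anteiso"),
    list("anteiso-C15:0", carbons = 15, db = 0, branch = "anteiso"),
    list("i-C13:0",  carbons = 13, db = 0, branch = "iso"),
    list("iso-C17:0", carbons = 17, db = 0, branch = "iso"),
    list("C18:1n7c", carbons = 18, db = 1, geometry = "cis",
         db_position = "n7"),
    list("C18:1n9t", carbons = 18, db = 1, geometry = "trans",
         db_position = "n9"),
    list("C16:1cis7", carbons = 16, db = 1, geometry = "cis",
         db_position = "7"),
    list("C16:1trans9", carbons = 16, db = 1, geometry = "trans"),
    list("C16:1c",   carbons = 16, db = 1, geometry = "cis"),
    list("2OH-C14:0", carbons = 14, db = 0, hydroxyl = 2L),
    list("3OH-C12:0", carbons = 12, db = 0, hydroxyl = 3L),
    list("cyclo-C17:0", carbons = 17, db = 0, cyclic = TRUE),
    list("C20:5n3",  carbons = 20, db = 5),
    list("C19:0",    carbons = 19, db = 0))
  for (cs in cases) {
    d <- parse_fa_label(cs[[1]])
    expect_equal(d$carbons, cs$carbons, info = cs[[1]])
    expect_equal(d$double_bonds, cs$db, info = cs[[1]])
    if (!is.null(cs$branch)) expect_equal(d$branch, cs$branch, info = cs[[1]])
    if (!is.null(cs$geometry))
      expect_equal(d$geometry, cs$geometry, info = cs[[1]])
    if (!is.null(cs$db_position))
      expect_equal(d$db_position, cs$db_position, info = cs[[1]])
    if (!is.null(cs$hydroxyl))
      expect_equal(d$hydroxyl_positions, cs$hydroxyl, info = cs[[1]])
    if (!is.null(cs$cyclic)) expect_true(d$cyclic, info = cs[[1]])
  }
})

test_that("parsing is case-insensitive and dialect variants are equivalent", {
  canon <- format(parse_fa_label("a-C15:0"))
  for (v in c("aC15:0", "A-c15:0", "ANTEISO-C15:0"))
    expect_equal(format(parse_fa_label(v)), canon)
  expect_equal(format(parse_fa_label("c18:1N7C")),
               format(parse_fa_label("C18:1n7c")))
})

test_that("unparseable labels raise a parse error naming the token", {
  expect_error(parse_fa_label("notafattyacid"), class = "fa_parse_error")
  expect_error(parse_fa_label("X-C16:0"), class = "fa_parse_error")
  expect_error(parse_fa_label("C16:0zz"), regexp = "zz")
  expect_error(parse_fa_label("C16"), class = "fa_parse_error")
  expect_error(parse_fa_label(""), regexp = "non-empty")
  # geometry without a double bond violates the descriptor invariants
  expect_error(parse_fa_label("C16:0c"), class = "fa_parse_error")
  # anteiso needs at least 5 carbons
  expect_error(parse_fa_label("a-C4:0"), class = "fa_parse_error")
})

test_that("descriptor invariants are enforced", {
  expect_error(fa_descriptor(1), regexp = ">= 2")
  expect_error(fa_descriptor(16, -1), regexp = "non-negative")
  expect_error(fa_descriptor(4, 3), regexp = "too large")
  expect_error(fa_descriptor(4, branch = "anteiso"), regexp = "anteiso")
  expect_error(fa_descriptor(16, 0, geometry = "cis"), regexp = "double bond")
  expect_error(fa_descriptor(16, hydroxyl_positions = 20), regexp = "2..carbons")
})

test_that("round trip: canonical rendering reparses to the same descriptor", {
  labels <- c("a-C15:0", "i-C13:0", "C18:1n7c", "C16:1cis7", "2OH-C14:0",
              "cyclo-C17:0", "C20:5n3", "C16:0", "C18:1t")
  for (l in labels) {
    d1 <- parse_fa_label(l)
    d2 <- parse_fa_label(format(d1))
    d1$raw_label <- d2$raw_label <- NULL
    expect_equal(d1, d2, info = l)
  }
})

test_that("chain-length classes are total and monotone over carbons 2..24", {
  expected <- c(rep("SCFA", 4),        # 2..5
                "MCFA",                # 6 (boundary, assigned to MCFA)
                rep("MCFA", 6),        # 7..12
                rep("LCFA", 9),        # 13..21
                rep("VLCFA", 3))       # 22..24
  got <- vapply(2:24, function(n)
    chain_length_class(fa_descriptor(n)), character(1))
  expect_equal(got, expected)
  expect_equal(chain_length_class(fa_descriptor(25)), "out_of_range")
  expect_equal(chain_length_class(fa_descriptor(6), c6_class = "SCFA"), "SCFA")
  # monotone: class index never decreases with carbon count
  rank <- match(got, c("SCFA", "MCFA", "LCFA", "VLCFA"))
  expect_true(all(diff(rank) >= 0))
})

test_that("structural classification partitions every descriptor", {
  grid <- expand.grid(db = 0:2, branch = c("none", "iso", "anteiso"),
                      oh = c(FALSE, TRUE), cyclic = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  classes <- c("cyclic_FA", "hydroxy_FA", "PUFA", "n_MUFA", "br_SFA",
               "n_SFA", "br_UFA_unknown")
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    d <- fa_descriptor(16, g$db, g$branch,
                       hydroxyl_positions = if (g$oh) 3L else integer(),
                       cyclic = g$cyclic)
    got <- structural_class(d)
    expect_length(got, 1)
    expect_true(got %in% classes)
    # precedence table
    want <- if (g$cyclic) "cyclic_FA"
      else if (g$oh) "hydroxy_FA"
      else if (g$db >= 2) "PUFA"
      else if (g$db == 1 && g$branch == "none") "n_MUFA"
      else if (g$db == 0 && g$branch != "none") "br_SFA"
      else if (g$db == 0) "n_SFA"
      else "br_UFA_unknown"
    expect_equal(got, want)
  }
})

test_that("profile summary matches an independent group-by oracle", {
  labels <- c("a-C15:0", "i-C15:0", "C16:0", "C18:0", "C16:1n7c", "C18:1n7c",
              "C20:5n3", "2OH-C12:0", "cyclo-C17:0", "C14:0")
  w <- c(20, 10, 15, 5, 18, 12, 6, 4, 6, 4)
  prof <- data.frame(sample_id = "s1", fa_label = labels, mass_mg = w)
  s <- summarize_profile(prof, minor_threshold_pct = 1)
  # oracle: direct group-by on hand-assigned classes
  cls <- vapply(labels, function(l) structural_class(parse_fa_label(l)), "")
  pct <- 100 * w / sum(w)
  for (cl in unique(cls)) {
    col <- if (cl == "br_UFA_unknown") cl else paste0(cl, "s")
    expect_equal(s[[col]], sum(pct[cls == cl]), info = cl)
  }
  expect_equal(s$minor_FA_pool, 0)
  expect_equal(s$iso_FAs, pct[2])
  expect_equal(s$anteiso_FAs, pct[1])
  expect_equal(s$cis_FAs, sum(pct[5:6]))
  expect_equal(s$LCFAs, sum(pct[c(1, 2, 3, 4, 5, 6, 7, 9, 10)]))
  expect_equal(s$MCFAs, pct[8])
})

test_that("minor acids are pooled and totals close to 100 percent", {
  prof <- data.frame(fa_label = c("C16:0", "C20:5n3"),
                     mass_mg = c(99.5, 0.5))
  s <- summarize_profile(prof, minor_threshold_pct = 1)
  expect_equal(s$minor_FA_pool, 0.5)
  expect_equal(s$PUFAs, 0)        # pooled, excluded from class sums
  expect_equal(s$n_SFAs, 99.5)
  struct <- s$PUFAs + s$n_SFAs + s$br_SFAs + s$n_MUFAs + s$hydroxy_FAs +
    s$cyclic_FAs + s$br_UFA_unknown + s$unknown_FAs + s$minor_FA_pool
  expect_equal(struct, 100)
})

test_that("unknown labels are carried as a class, never dropped", {
  prof <- data.frame(fa_label = c("C16:0", "mystery-peak"),
                     mass_mg = c(60, 40))
  s <- summarize_profile(prof)
  expect_equal(s$unknown_FAs, 40)
  expect_equal(s$n_SFAs + s$unknown_FAs + s$minor_FA_pool, 100)
})

test_that("summary percentages are invariant to uniform weight rescaling", {
  prof <- data.frame(fa_label = c("a-C15:0", "C16:0", "C16:1n7c", "C20:5n3"),
                     mass_mg = c(3, 4, 2, 1))
  s1 <- summarize_profile(prof)
  prof$mass_mg <- prof$mass_mg * 1234.5
  s2 <- summarize_profile(prof)
  expect_equal(s1, s2)
})

test_that("degenerate profiles error out", {
  expect_error(summarize_profile(data.frame(fa_label = "C16:0", mass_mg = 0)),
               regexp = "all-zero")
  expect_error(summarize_profile(data.frame(fa_label = "C16:0", mass_mg = -1)),
               regexp = "negative")
})
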