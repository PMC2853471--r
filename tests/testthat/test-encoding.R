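test_that("padding adds (W-1)/2 dummy residues per terminus", {
  # the window-17 case: 8 'X' at each side
  p <- pad_sequence("ACDEFG", window_config(17))
  expect_equal(nchar(p), 6 + 2 * 8)
  expect_equal(substr(p, 1, 8), "XXXXXXXX")
  expect_equal(substr(p, 9, 14), "ACDEFG")

  expect_equal(nchar(pad_sequence("ACDEF", window_config(3))), 7)
  expect_error(window_config(1), "odd integer >= 3")
  expect_error(window_config(4), "odd integer >= 3")
})

test_that("make_windows yields one centred window per residue", {
  expect_equal(make_windows("GAY", window_config(3)), c("XGA", "GAY", "AYX"))
  w17 <- make_windows("ACDEFGHIKLMNPQRSTVWY", window_config(17))
  expect_equal(substr(w17[1], 1, 8), "XXXXXXXX")
  expect_equal(make_windows("", window_config(3)), character(0))

  # property: window count = L, centre = residue, for random L and odd W
  set.seed(8)
  for (trial in 1:20) {
    L <- sample(1:60, 1)
    W <- sample(seq(3, 21, 2), 1)
    s <- paste(sample(aa_alphabet(FALSE), L, TRUE), collapse = "")
    win <- make_windows(s, window_config(W))
    expect_length(win, L)
    expect_true(all(nchar(win) == W))
    centres <- substr(win, (W - 1) / 2 + 1, (W - 1) / 2 + 1)
    expect_equal(paste(centres, collapse = ""), s)
  }
})

test_that("binary encoding is 21-per-position one-hot in the fixed alphabet order", {
  # Ala is the first symbol: 1 followed by 20 zeros
  a <- encode_binary("A")
  expect_equal(as.vector(a), c(1, rep(0, 20)))
  x <- encode_binary("X")
  expect_equal(which(as.vector(x) == 1), 21)

  win <- make_windows("GAY", window_config(5))
  m <- encode_binary(win)
  expect_equal(dim(m), c(3, 21 * 5))
  expect_true(all(rowSums(m) == 5))          # exactly W ones
  expect_true(all(m %in% c(0, 1)))
  # one 1 per 21-block
  for (b in 1:5) expect_true(all(rowSums(m[, (b - 1) * 21 + 1:21]) == 1))
  expect_error(encode_binary("GA?"), "illegal residue")
})

test_that("binary encoding is injective (patterns decode back)", {
  decode <- function(row) {
    W <- length(row) / 21
    paste(vapply(seq_len(W), function(b) {
      aa_alphabet()[which(row[(b - 1) * 21 + 1:21] == 1)]
    }, ""), collapse = "")
  }
  set.seed(2)
  pats <- vapply(1:25, function(i)
    paste(sample(aa_alphabet(), 7, TRUE), collapse = ""), "")
  m <- encode_binary(pats)
  expect_equal(vapply(seq_len(nrow(m)), function(i) decode(m[i, ]), ""), pats)
})

test_that("ASCII PSSM parsing checks shape and residue agreement", {
  sim <- simulate_chains(n_chains = 1, len_range = c(25, 25), seed = 6)
  prof <- simulate_pssm(sim$chains[[1]], sim$labels[[1]], seed = 6)
  lines <- write_pssm_ascii(prof)
  back <- parse_pssm_ascii(lines, sequence = sim$chains[[1]])
  expect_true(all(back$matrix == prof$matrix))
  expect_equal(dim(back$matrix), c(25, 20))

  # three-row fixture parses to a 3x20 matrix
  small <- write_pssm_ascii(prof$matrix[1:3, ], sequence = substr(sim$chains[[1]], 1, 3))
  expect_equal(dim(parse_pssm_ascii(small)$matrix), c(3, 20))

  # residue-column disagreement with the chain is an error
  wrong <- chartr("ACDEFGHIKLMNPQRSTVWY", "CADEFGHIKLMNPQRSTVWY",
                  sim$chains[[1]])
  if (wrong != sim$chains[[1]]) {
    expect_error(parse_pssm_ascii(lines, sequence = wrong), "disagrees")
  }
  expect_error(parse_pssm_ascii(lines, sequence = "ACD"), "rows but chain")
  expect_error(parse_pssm_ascii("no rows here"), "no PSSM rows")
})

test_that("PSSM window encoding scales logistically and zeroes the padding", {
  L <- 10
  zero <- matrix(0L, L, 20, dimnames = list(NULL, aa_alphabet(FALSE)))
  cfg <- window_config(5)
  m <- encode_pssm(zero, cfg = cfg)
  expect_equal(dim(m), c(L, 20 * 5))
  # centre residue 1: first two window positions are padding (exact 0),
  # the rest scale s(0) = 0.5
  expect_equal(unname(m[1, 1:40]), rep(0, 40))
  expect_equal(unname(m[1, 41:100]), rep(0.5, 60))
  # interior residues have no padding: all 0.5
  expect_true(all(m[3:(L - 2), ] == 0.5))
  # identity and div100 scalers
  one <- matrix(10L, L, 20)
  expect_true(all(encode_pssm(one, cfg = cfg, scaler = "identity")[5, ] == 10))
  expect_true(all(encode_pssm(one, cfg = cfg, scaler = "div100")[5, ] == 0.1))
})

test_that("feature matrix stacks chains with a faithful provenance index", {
  set.seed(3)
  chains <- c(c1 = paste(sample(aa_alphabet(FALSE), 10, TRUE), collapse = ""),
              c2 = paste(sample(aa_alphabet(FALSE), 7, TRUE), collapse = ""))
  labels <- lapply(chains, function(s) as.integer(seq_len(nchar(s)) %% 2))
  fm <- build_feature_matrix(chains, labels, mode = "binary",
                             cfg = window_config(17))
  expect_equal(nrow(fm$x), 17)
  expect_equal(ncol(fm$x), 357)          # 21 * 17
  expect_equal(fm$index$chain_id, rep(c("c1", "c2"), c(10, 7)))
  expect_equal(fm$index$residue, c(1:10, 1:7))
  expect_equal(fm$y, unlist(labels, use.names = FALSE))
  # provenance decodes rows back to (chain, residue): row 12 is c2 residue 2
  expect_equal(fm$index[12, ], data.frame(chain_id = "c2", residue = 2L),
               ignore_attr = TRUE)

  expect_error(build_feature_matrix(chains, labels, mode = "pssm",
                                    cfg = window_config(5)),
               "requires a profile")
})
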