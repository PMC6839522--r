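write_lines_tmp <- function(lines, ext = ".nex") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

nexus_fixture <- function() write_lines_tmp(c(
  "#NEXUS",
  "BEGIN DATA;",
  "DIMENSIONS NTAX=4 NCHAR=5;",
  "FORMAT DATATYPE=STANDARD SYMBOLS=\"0123\" MISSING=? GAP=-;",
  "MATRIX",
  "Alpha_one   01{01}?-",
  "'Beta two'  10(12)0?",
  "Gamma       002-1",
  "Delta       11101",
  ";",
  "END;"))

test_that("NEXUS parsing handles states, polymorphism, missing and inapplicable", {
  m <- read_nexus(nexus_fixture())
  expect_equal(dim(m), c(4L, 5L))
  expect_equal(m$taxa, c("Alpha one", "Beta two", "Gamma", "Delta"))
  # cell (1,3) is {01} -> bits 0 and 1
  expect_equal(m$states[1, 3], bitwOr(1L, 2L))
  expect_equal(m$states[2, 3], bitwOr(2L, 4L))   # (12)
  expect_equal(m$states[1, 4], 0L)               # ?
  expect_false(m$inapplicable[1, 4])
  expect_equal(m$states[1, 5], 0L)               # -
  expect_true(m$inapplicable[1, 5])
})

test_that("a 1-taxon 1-character '?' file parses to a single missing cell", {
  f <- write_lines_tmp(c("#NEXUS", "BEGIN DATA;",
                         "DIMENSIONS NTAX=1 NCHAR=1;",
                         "FORMAT MISSING=? GAP=-;", "MATRIX", "only ?", ";",
                         "END;"))
  m <- read_nexus(f)
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(m$states[1, 1], 0L)
  expect_false(m$inapplicable[1, 1])
})

test_that("malformed matrices give located parse errors", {
  ragged <- write_lines_tmp(c("#NEXUS", "BEGIN DATA;",
                              "DIMENSIONS NTAX=2 NCHAR=3;", "MATRIX",
                              "A 010", "B 01", ";", "END;"))
  expect_error(read_nexus(ragged), "ragged.*B", class = "maxpars_parse_error")
  badsym <- write_lines_tmp(c("#NEXUS", "BEGIN DATA;",
                              "DIMENSIONS NTAX=2 NCHAR=3;", "MATRIX",
                              "A 0x0", "B 010", ";", "END;"))
  expect_error(read_nexus(badsym), "unexpected symbol",
               class = "maxpars_parse_error")
  dup <- matrix("0", 2, 2)
  expect_error(char_matrix(dup, taxa = c("A b", "A_b")), "duplicate")
  nodata <- write_lines_tmp(c("#NEXUS", "BEGIN TREES;", "END;"))
  expect_error(read_nexus(nodata), "no DATA", class = "maxpars_parse_error")
})

test_that("NEXUS and TNT writers round-trip cell-identically", {
  set.seed(31)
  for (rep in 1:5) {
    m <- rand_matrix(7, 12, k = 3, missing_p = 0.2, poly_p = 0.1)
    f <- tempfile(fileext = ".nex")
    write_nexus(m, f)
    m2 <- read_nexus(f)
    expect_identical(m2$states, m$states)
    expect_identical(m2$inapplicable, m$inapplicable)
    expect_identical(m2$taxa, m$taxa)
    ft <- tempfile(fileext = ".tnt")
    write_tnt(m, ft)
    m3 <- read_tnt(ft)
    expect_identical(m3$states, m$states)
    expect_identical(m3$taxa, m$taxa)
  }
})

test_that("polymorphic cells render as bracket tokens in both dialects", {
  m <- char_matrix(rbind(A = c("{01}", "1"), B = c("0", "1"),
                         C = c("0", "0"), D = c("1", "0")))
  f <- tempfile(); write_nexus(m, f)
  expect_true(any(grepl("\\{01\\}", readLines(f))))
  ft <- tempfile(); write_tnt(m, ft)
  expect_true(any(grepl("\\[01\\]", readLines(ft))))
  mt <- read_tnt(ft)
  expect_equal(mt$states[1, 1], 3L)
})

test_that("minimal TNT xread parses with TNT dimension order (nchar ntax)", {
  f <- write_lines_tmp(c("xread", "'three taxa two chars'", "2 3",
                         "ta 01", "tb 0[01]", "tc 10", ";"), ext = ".tnt")
  m <- read_tnt(f)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$states[2, 2], 3L)
})

test_that("NEXUS reader agrees with ape on a plain fixture", {
  skip_if_not_installed("ape")
  set.seed(8)
  m <- rand_matrix(6, 10, k = 3, missing_p = 0.15)
  f <- tempfile(fileext = ".nex")
  write_nexus(m, f)
  ap <- ape::read.nexus.data(f)
  expect_equal(names(ap), gsub(" ", "_", m$taxa))
  ours <- apply(m$states, 1:2, function(x)
    if (x == 0L) "?" else as.character(maxpars:::mask_states(x)))
  theirs <- do.call(rbind, ap)
  expect_equal(unname(ours), unname(theirs))
})

test_that("matrix_summary counts scored cells and conserves totals", {
  m <- char_matrix(rbind(A = c("0", "1", "?", "{01}"),
                         B = c("?", "?", "-", "0"),
                         C = c("1", "1", "0", "0")))
  s <- matrix_summary(m)
  expect_equal(s$taxa$scored, c(3, 1, 4))
  expect_equal(s$taxa$polymorphic, c(1, 0, 0))
  expect_equal(s$taxa$inapplicable, c(0, 1, 0))
  # conservation: per-taxon scored sums equal total non-empty cells
  expect_equal(sum(s$taxa$scored), sum(m$states != 0L))
  allmiss <- char_matrix(matrix("?", 1, 4), taxa = "x")
  expect_equal(matrix_summary(allmiss)$taxa$scored, 0)
})

test_that("a study-scale synthetic matrix round-trips and stays small", {
  set.seed(77)
  sim <- simulate_matrix(simulation_config(rng_seed = 77))
  expect_equal(dim(sim$matrix), c(114L, 202L))
  f <- tempfile(fileext = ".nex")
  write_nexus(sim$matrix, f)
  expect_lt(file.size(f), 1e6)
  m2 <- read_nexus(f)
  expect_identical(m2$states, sim$matrix$states)
  expect_identical(m2$taxa, sim$matrix$taxa)
})
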