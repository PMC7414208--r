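# shared fixtures and generators

overall_table <- function() table2x2(106, 33, 110, 29)

# random table with all cells positive, arms of size 2..n_max
random_positive_table <- function(n_max = 200) {
  n1 <- sample(2:n_max, 1)
  n2 <- sample(2:n_max, 1)
  a <- sample(seq_len(n1 - 1), 1)
  d <- sample(seq_len(n2 - 1), 1)
  table2x2(a, n1 - a, n2 - d, d)
}

expect_same_table <- function(x, y) {
  expect_identical(c(x$a, x$b, x$c, x$d), c(y$a, y$b, y$c, y$d))
}

# bare records, without provenance/class, for exact round-trip comparison
records_of <- function(ds) {
  d <- as.data.frame(ds)
  attr(d, "provenance") <- NULL
  rownames(d) <- NULL
  d
}
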