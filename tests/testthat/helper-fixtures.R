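# shared fixtures built in code; no binary data anywhere

panel <- pah_congeners()

# a tibble with the 16 congener columns set from a 16-vector or a function(i)
congener_row_tbl <- function(...) {
  rows <- list(...)
  tibble::as_tibble(as.data.frame(do.call(rbind, rows)) |> stats::setNames(panel))
}

# small positive concentration table with metadata, n rows
toy_concentration <- function(n = 6, seed = 99) {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n * 16, log(50), 0.5), nrow = n,
                 dimnames = list(NULL, panel))
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      region = rep(c("A", "B"), length.out = n),
      year = 2010L
    ),
    tibble::as_tibble(as.data.frame(vals))
  )
}

# write a concentration CSV and return its path
write_toy_csv <- function(data, name = "toy.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(data, path)
  path
}

# do two vectors of labels describe the same partition?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

truth_blocks <- c(
  Nap = 1L, Acy = 2L, Ace = 3L, Flo = 3L, Phe = 3L, Ant = 3L,
  Flu = 3L, Pyr = 3L, BaA = 4L, Chr = 4L, BbF = 4L, BkF = 4L,
  BaP = 4L, IcdP = 4L, BghiP = 4L, DahA = 4L
)

characteristic_four <- c("Nap", "Acy", "Phe", "BaA")

# brute-force normal-equations OLS used as the independent oracle
ols_oracle <- function(y, X, intercept = TRUE) {
  if (intercept) X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
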