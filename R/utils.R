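`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise log(sum(exp(.))) guarding against underflow; rows that are all
# -Inf stay -Inf rather than producing NaN.
logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# Coerce cases to an n x d numeric matrix; a bare vector is read as n
# univariate cases when d == 1, as one d-dimensional case otherwise.
as_cases <- function(x, d) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    x <- if (d == 1L) matrix(as.numeric(x), ncol = 1L) else matrix(as.numeric(x), nrow = 1L)
  }
  storage.mode(x) <- "double"
  if (ncol(x) != d) {
    stop("case table has ", ncol(x), " feature column(s); the model expects ", d)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("case table contains non-finite values")
  }
  x
}

run_seeded <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# YAML 1.1 resolves the bare scalars y/n/yes/no/on/off as booleans,
# which mangles feature names like "n"; keep only true/false-like words
# as logicals and leave the short forms verbatim.
read_yaml_strict <- function(path) {
  keep <- function(x) {
    lx <- tolower(x)
    if (lx %in% c("true", "yes", "on")) TRUE
    else if (lx %in% c("false", "no", "off")) FALSE
    else x
  }
  bool <- function(x) {
    lx <- tolower(x)
    if (lx %in% c("y", "n")) x else keep(x)
  }
  yaml::read_yaml(path, handlers = list("bool#yes" = bool, "bool#no" = bool))
}

# All permutations of 1..n (n small); used to align fitted mixture
# components with truth classes.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, ifelse(sub >= i, sub + 1L, sub)))
  }
  unname(out)
}
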