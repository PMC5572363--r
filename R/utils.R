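# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used wherever a documented seed argument must make one call
# reproducible in isolation.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed
#'
#' Mixes a master seed with any number of integer or character tags
#' (linkage-group ids, proportion levels, replicate numbers) into a new
#' seed in `[1, 2^31 - 2]`. The mixing is a multiplicative-congruential
#' hash, so any single experimental record can be regenerated in
#' isolation from the master seed and its coordinates.
#'
#' @param master integer master seed.
#' @param ... integer or character tags identifying the sub-stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  tags <- list(...)
  x <- as.numeric(master) %% 2147483647
  for (tag in tags) {
    ks <- if (is.character(tag)) utf8ToInt(paste(tag, collapse = "/"))
          else as.numeric(tag)
    for (k in ks) {
      # 69069 * 2^31 < 2^53: exact in double arithmetic
      x <- (x * 69069 + (k %% 2147483647) + 1) %% 2147483647
    }
  }
  as.integer(x %% 2147483645 + 1)
}

# Convert an A/B/U character call matrix to the +1/-1/0 numeric coding
# used by the pairwise machinery.
geno_numeric <- function(geno) {
  x <- matrix(0, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  x[geno == "A"] <- 1
  x[geno == "B"] <- -1
  x
}

check_geno <- function(geno) {
  if (!is.matrix(geno) || !is.character(geno))
    stop("genotype matrix must be a character matrix with calls A/B/U")
  bad <- !(geno %in% c("A", "B", "U"))
  if (any(bad))
    stop("unknown genotype call(s): ",
         paste(unique(geno[bad]), collapse = ", "))
  if (is.null(colnames(geno)) || anyDuplicated(colnames(geno)))
    stop("genotype matrix needs unique marker (column) names")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("line_%03d", seq_len(nrow(geno)))
  invisible(geno)
}
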