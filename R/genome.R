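#' Default genome model
#'
#' Approximate autosome lengths (bp) for a human-like diploid genome model.
#' Mutations are placed uniformly over the 22 autosomes; burden is reported
#' per diploid genome of `diploid_size` bases (default 6.2e9, i.e. 2 x 3.1e9).
#'
#' @param diploid_size total diploid genome size in bases used for burden
#'   scaling.
#' @return a list with `chrom` (names), `length` (bp per autosome) and
#'   `diploid_size`.
#' @export
default_genome <- function(diploid_size = 6.2e9) {
  len <- c(
    249e6, 243e6, 198e6, 191e6, 181e6, 171e6, 159e6, 146e6,
    141e6, 136e6, 135e6, 134e6, 115e6, 107e6, 103e6, 90e6,
    81e6, 78e6, 59e6, 63e6, 48e6, 51e6
  )
  list(
    chrom = paste0("chr", seq_len(22)),
    length = len,
    diploid_size = diploid_size
  )
}

# Sample n distinct genomic sites uniformly over the genome model.
# Returns a data.frame(chrom, pos, ref, alt); positions are 1-based.
# Infinite-sites: duplicate (chrom, pos) draws are rejected and redrawn.
sample_sites <- function(n, genome = default_genome()) {
  if (n == 0L) {
    return(data.frame(
      chrom = character(), pos = integer(),
      ref = character(), alt = character(),
      stringsAsFactors = FALSE
    ))
  }
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    ci <- sample.int(length(genome$length), k, replace = TRUE,
                     prob = genome$length)
    pos <- floor(stats::runif(k) * genome$length[ci]) + 1
    data.frame(chrom = genome$chrom[ci], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }
  sites <- draw(n)
  key <- function(s) paste(s$chrom, s$pos)
  while (anyDuplicated(key(sites))) {
    dup <- duplicated(key(sites))
    sites[dup, ] <- draw(sum(dup))
  }
  sites$ref <- sample(bases, n, replace = TRUE)
  alt_off <- sample.int(3L, n, replace = TRUE)
  sites$alt <- bases[(match(sites$ref, bases) - 1L + alt_off) %% 4L + 1L]
  sites
}
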