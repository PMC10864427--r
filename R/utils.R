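# internal helpers shared across modules

# The 20 canonical amino acids (no stop, no selenocysteine/ambiguity codes);
# external predictors accept these letters only.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.HLA_RE <- "^HLA-[ABC]\\*[0-9]{2}:[0-9]{2}$"

# Deterministic substream seed for a named component: a polynomial string
# hash folded with the master seed, kept below 2^31 so set.seed() accepts it.
# Adding a generator never perturbs the streams of existing ones.
.substream <- function(seed, component) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(component) == 1L)
  h <- 0
  for (code in utf8ToInt(component)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 2654435) %% 2147483647)
}

# round-half-up at `digits` decimals (sign-aware); base round() is half-even
.roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.checkCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.checkPeptide <- function(peptide) {
  if (length(peptide) != 1L || is.na(peptide) || !nzchar(peptide))
    stop("peptide must be a single non-empty string", call. = FALSE)
  bad <- setdiff(strsplit(peptide, "")[[1]], .AA20)
  if (length(bad))
    stop(sprintf("peptide '%s' contains non-canonical residue(s): %s",
                 peptide, paste(unique(bad), collapse = ", ")), call. = FALSE)
  invisible(peptide)
}

.checkAllele <- function(allele) {
  bad <- allele[!grepl(.HLA_RE, allele)]
  if (length(bad))
    stop(sprintf("allele(s) not in HLA-[ABC]*NN:NN form: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(allele)
}
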