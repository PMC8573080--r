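## Shared helpers: typed errors, chromosome-name normalisation, TSV io.

cogsError <- function(msg, class) {
  stop(structure(class = c(class, "cogsr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

formatError      <- function(msg) cogsError(msg, "cogsr_format_error")
consistencyError <- function(msg) cogsError(msg, "cogsr_consistency_error")
configError      <- function(msg) cogsError(msg, "cogsr_config_error")
dataError        <- function(msg) cogsError(msg, "cogsr_data_error")

## Canonical chromosome dialect: "chr"-prefixed ("chr1", "chrX"). Sources in
## either dialect are unified at load; downstream joins therefore never mix.
normChrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x, ignore.case = TRUE), sub("^[Cc][Hh][Rr]", "chr", x),
         paste0("chr", x))
}

isSexChrom <- function(chrom) normChrom(chrom) %in% c("chrX", "chrY")

## TSV io with transparent gzip (by .gz suffix). Number formatting is pinned
## so identical in-memory tables serialise byte-identically across runs.
writeTsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) trimws(formatC(v, digits = 6, format = "g")))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

readTsv <- function(path, header = TRUE, col.names, comment.char = "") {
  if (!file.exists(path)) formatError(paste0("file not found: ", path))
  args <- list(path, header = header, sep = "\t", stringsAsFactors = FALSE,
               comment.char = comment.char, check.names = FALSE)
  if (!missing(col.names)) args$col.names <- col.names
  do.call(utils::read.delim, args)
}

## Seed derivation for per-table sub-streams; keeps derived seeds < 2^31.
subSeed <- function(seed, offset) (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
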