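DNA_BASES <- c("A", "C", "G", "T")

# Parse a CIGAR string into parallel op/length vectors.
# Returns list(op = character, len = integer). Ops restricted to the SAM
# alphabet; anything else is a hard error.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(list(op = character(0), len = integer(0)))
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  }
  n <- nchar(toks)
  list(
    op  = substr(toks, n, n),
    len = as.integer(substr(toks, 1L, n - 1L))
  )
}

# Number of query bases consumed by a CIGAR (excluding hard clips).
cigar_query_length <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
}

# Number of reference bases consumed by a CIGAR.
cigar_reference_length <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

# Tiny polynomial rolling hash over a character scalar; used only to stamp
# output files with a short configuration fingerprint.
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Header comment lines written at the top of every TSV output.
output_header <- function(config) {
  cfg_str <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  inputs <- unlist(config[grepl("path$|file$", names(config))], use.names = FALSE)
  inputs <- inputs[!is.na(inputs) & file.exists(as.character(inputs))]
  sums <- if (length(inputs)) {
    paste(sprintf("%s=%s", basename(inputs), tools::md5sum(as.character(inputs))),
          collapse = " ")
  } else {
    "none"
  }
  c(
    sprintf("# gtamp %s", as.character(utils::packageVersion("gtamp"))),
    sprintf("# config_hash: %s", config_fingerprint(cfg_str)),
    sprintf("# input_md5: %s", sums)
  )
}

write_tsv_with_header <- function(df, path, config = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
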