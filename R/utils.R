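# shared internal helpers

# Delimiter auto-detection by header sniffing: tab wins if present,
# otherwise comma.  A documented column map can rename on top of this.
read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    colClasses = "character", quote = "\"",
                    comment.char = "")
}

write_delim_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

# round half away from zero (report-table convention; matches printed
# values like 56.3%)
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# labelled square matrix reader/writer (first column = row labels)
write_square_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write_delim_tsv(df, path)
}

read_square_matrix <- function(path) {
  df <- read_delim_auto(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_num <- function(x) suppressWarnings(as.numeric(x))

# permutation / bootstrap P-value with +1 correction
perm_pvalue <- function(n_as_extreme, n_perm) (n_as_extreme + 1) / (n_perm + 1)
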