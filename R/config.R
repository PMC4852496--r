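# Plain-text I/O shared by all modules: TSV tables with '#' provenance
# comments, and key=value config files.

.write_tsv <- function(d, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.provenance_header <- function(seed = NULL, params = NULL) {
  h <- sprintf("cmzclone %s", as.character(utils::packageVersion("cmzclone")))
  if (!is.null(seed)) h <- c(h, sprintf("seed=%s", seed))
  if (!is.null(params))
    h <- c(h, paste(names(params), unlist(params), sep = "=", collapse = " "))
  h
}

#' Read and write key-value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' converted to numeric where possible; comma-separated values become
#' vectors. A division-mode schedule is encoded as
#' `windows = 0:8:1,0,0;8:15:0.2,0.4,0.4;15:Inf:0.2,0,0.8`
#' (`start:end:pPP,pPD,pDD` separated by `;`) and decoded with
#' [parse_schedule()].
#'
#' @param path File path.
#' @param config Named list to write.
#' @return `read_config` returns a named list.
#' @name config_io
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!grepl("[;:]", val)) {
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      if (!anyNA(num)) val <- num else if (length(parts) > 1) val <- parts
    }
    out[[key]] <- val
  }
  out
}

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  enc <- vapply(config, function(v) paste(as.character(v), collapse = ","),
                character(1))
  writeLines(paste(names(config), enc, sep = " = "), path)
  invisible(path)
}

#' @rdname config_io
#' @param text Schedule string (see Details).
#' @export
parse_schedule <- function(text) {
  wins <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- lapply(wins, function(w) as.numeric(strsplit(w, "[:,]")[[1]]))
  if (any(lengths(parts) != 5)) stop("malformed schedule window")
  m <- do.call(rbind, parts)
  mode_schedule(breaks = m[-nrow(m), 2], probs = m[, 3:5])
}
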