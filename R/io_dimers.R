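# Dimer i/o: each dimer is one extended-XYZ frame holding both monomers,
# with the monomer split (`mol1_atoms`), the reference dispersion energy
# and the nearest-atom distance on the comment line.

#' Write dimer records to an extended-XYZ file
#'
#' @param dimers a `"dimer_set"`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dimers <- function(dimers, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (rec in dimers) {
    n1 <- nrow(rec$coords1); n2 <- nrow(rec$coords2)
    comment <- sprintf(
      'Properties=species:S:1:type:S:1:pos:R:3 mol1_atoms=%d distance=%s%s Label="%s"',
      n1, fmt_num(rec$distance),
      if (!is.null(rec$energy)) paste0(" energy=", fmt_num(rec$energy)) else "",
      rec$label)
    writeLines(c(as.character(n1 + n2), comment), con)
    el <- c(rec$elements1, rec$elements2)
    ty <- c(rec$types1, rec$types2)
    xy <- rbind(rec$coords1, rec$coords2)
    for (i in seq_len(n1 + n2))
      writeLines(paste(el[i], ty[i], paste(fmt_num(xy[i, ]), collapse = " ")),
                 con)
  }
  invisible(path)
}

#' Read dimer records from an extended-XYZ file
#'
#' @param path input written by [write_dimers()]
#' @return a `"dimer_set"`
#' @export
read_dimers <- function(path) {
  lines <- readLines(path)
  recs <- list(); ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat)) stop(sprintf("malformed atom count at line %d", ln))
    kv <- parse_comment_kv(lines[ln + 1L])
    n1 <- as.integer(kv$mol1_atoms)
    if (is.na(n1)) stop("dimer frame lacks mol1_atoms")
    toks <- strsplit(trimws(lines[(ln + 2L):(ln + 1L + nat)]), "\\s+")
    el <- vapply(toks, `[`, "", 1)
    ty <- vapply(toks, `[`, "", 2)
    xy <- t(vapply(toks, function(t_) as.numeric(t_[3:5]), numeric(3)))
    recs[[length(recs) + 1L]] <- list(
      coords1 = xy[seq_len(n1), , drop = FALSE],
      coords2 = xy[(n1 + 1):nat, , drop = FALSE],
      types1 = ty[seq_len(n1)], types2 = ty[(n1 + 1):nat],
      elements1 = el[seq_len(n1)], elements2 = el[(n1 + 1):nat],
      distance = as.numeric(kv$distance),
      energy = if (!is.null(kv$energy)) as.numeric(kv$energy),
      label = if (!is.null(kv$Label)) kv$Label else "")
    ln <- ln + 2L + nat
  }
  structure(recs, class = "dimer_set")
}
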