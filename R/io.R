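# Extended-XYZ i/o for conformations (forces in extra per-atom columns,
# box / energy / label on the comment line) and the JSON force-field
# parameter document.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write conformations to an extended-XYZ file
#'
#' One frame per block: atom count, a comment line with
#' `Properties=...`, optional `Lattice="..."` (orthorhombic), optional
#' `energy=...` and `Label=...`, then one line per atom with element,
#' optional atom type column, coordinates, and optional force columns.
#'
#' @param confs [conformation_set()] (or single [conformation()])
#' @param top matching [topology()] (supplies elements and types)
#' @param path output file
#' @param types write the atom type as an extra string column
#' @return `path`, invisibly
#' @export
write_conformations <- function(confs, top, path, types = TRUE) {
  if (inherits(confs, "conformation")) confs <- conformation_set(list(confs))
  con <- file(path, "w"); on.exit(close(con))
  for (cf in confs) {
    nat <- nrow(cf$coords)
    props <- paste0("species:S:1", if (types) ":type:S:1", ":pos:R:3",
                    if (!is.null(cf$forces)) ":forces:R:3")
    comment <- paste0("Properties=", props)
    if (!is.null(cf$box))
      comment <- paste0(comment, sprintf(' Lattice="%s 0 0 0 %s 0 0 0 %s"',
                                         fmt_num(cf$box[1]), fmt_num(cf$box[2]),
                                         fmt_num(cf$box[3])))
    if (!is.null(cf$energy))
      comment <- paste0(comment, " energy=", fmt_num(cf$energy))
    if (nzchar(cf$label))
      comment <- paste0(comment, ' Label="', cf$label, '"')
    writeLines(c(as.character(nat), comment), con)
    for (i in seq_len(nat)) {
      fields <- c(top$atoms$element[i],
                  if (types) top$atoms$type[i],
                  fmt_num(cf$coords[i, ]),
                  if (!is.null(cf$forces)) fmt_num(cf$forces[i, ]))
      writeLines(paste(fields, collapse = " "), con)
    }
  }
  invisible(path)
}

parse_comment_kv <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (k in seq_along(m)) {
    tok <- substr(line, m[k], m[k] + attr(m, "match.length")[k] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

#' Read conformations from an extended-XYZ file
#'
#' Parses the `Properties=` descriptor to locate coordinate and force
#' columns; recovers orthorhombic boxes from `Lattice`, frame labels and
#' energies from the comment line. Round-trips bit-identically with
#' [write_conformations()] for values it wrote.
#'
#' @param path input file
#' @return list with `confs` (a [conformation_set()]), `elements`,
#'   `types` (per-atom, from the first frame; `NULL` if absent)
#' @export
read_conformations <- function(path) {
  lines <- readLines(path)
  frames <- list(); elements <- NULL; types <- NULL
  ln <- 1L; fi <- 0L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat <= 0)
      stop(sprintf("malformed atom count at line %d", ln))
    fi <- fi + 1L
    if (ln + 1L + nat > length(lines))
      stop(sprintf("truncated frame %d (starting at line %d)", fi, ln))
    kv <- parse_comment_kv(lines[ln + 1L])
    props <- if (!is.null(kv$Properties)) kv$Properties else "species:S:1:pos:R:3"
    spec <- strsplit(props, ":", fixed = TRUE)[[1]]
    cols <- list(); at <- 1L
    for (k in seq(1, length(spec), by = 3)) {
      nm <- spec[k]; width <- as.integer(spec[k + 2])
      cols[[nm]] <- at:(at + width - 1L)
      at <- at + width
    }
    if (is.null(cols$pos)) stop("Properties descriptor lacks pos")
    body <- lines[(ln + 2L):(ln + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < at - 1L)
    if (length(bad))
      stop(sprintf("malformed atom line at line %d", ln + 1L + bad[1]))
    get_cols <- function(idx) {
      m <- t(vapply(toks, function(t_) as.numeric(t_[idx]),
                    numeric(length(idx))))
      if (length(idx) == 1) matrix(m, ncol = 1) else m
    }
    coords <- get_cols(cols$pos)
    forces <- if (!is.null(cols$forces)) get_cols(cols$forces)
    el <- vapply(toks, function(t_) t_[cols$species[1]], character(1))
    ty <- if (!is.null(cols$type))
      vapply(toks, function(t_) t_[cols$type[1]], character(1))
    if (is.null(elements)) { elements <- el; types <- ty }
    box <- NULL
    if (!is.null(kv$Lattice)) {
      lat <- as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]])
      if (length(lat) != 9) stop("Lattice must have 9 components")
      off <- abs(lat[c(2, 3, 4, 6, 7, 8)])
      if (any(off > 1e-10)) stop("only orthorhombic lattices are supported")
      box <- lat[c(1, 5, 9)]
    }
    energy <- if (!is.null(kv$energy)) as.numeric(kv$energy)
    label <- if (!is.null(kv$Label)) kv$Label else ""
    frames[[fi]] <- conformation(coords, forces = forces, box = box,
                                 label = label, energy = energy)
    ln <- ln + 2L + nat
  }
  list(confs = conformation_set(frames), elements = elements, types = types)
}

# ---- force-field parameter document (JSON) ----------------------------

FF_UNITS <- list(length = "angstrom", energy = "kcal/mol", charge = "e",
                 angle = "rad")

#' Write a force field to its JSON parameter document
#'
#' @param ff a [forcefield()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_forcefield <- function(ff, path) {
  doc <- list(units = FF_UNITS, damping = ff$damping,
              atom_types = ff$atom_types, bonds = ff$bonds,
              angles = ff$angles, torsions = ff$torsions, pairs = ff$pairs)
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a force field from its JSON parameter document
#'
#' Validates the units header (required), the damping tag (defaults to
#' `"rational"` with a warning for legacy files), rejects unknown
#' top-level keys, and re-runs all [forcefield()] invariants — including
#' the rule that dispersion coefficients may sit only on carbon-carbon
#' pairs.
#'
#' @param path input file
#' @return a [forcefield()]
#' @export
read_forcefield <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("units", "damping", "atom_types", "bonds", "angles",
             "torsions", "pairs")
  extra <- setdiff(names(doc), known)
  if (length(extra)) stop("unknown key(s) in parameter file: ",
                          paste(extra, collapse = ", "))
  if (is.null(doc$units)) stop("parameter file lacks the units header")
  for (u in names(FF_UNITS)) {
    if (!identical(doc$units[[u]], FF_UNITS[[u]]))
      stop(sprintf("unsupported %s unit '%s' (internal unit is '%s')",
                   u, doc$units[[u]], FF_UNITS[[u]]))
  }
  damping <- doc$damping
  if (is.null(damping)) {
    warning("parameter file lacks a damping tag; assuming 'rational'")
    damping <- "rational"
  }
  forcefield(as.data.frame(doc$atom_types), as.data.frame(doc$bonds),
             as.data.frame(doc$angles), as.data.frame(doc$torsions),
             as.data.frame(doc$pairs), damping = damping)
}

#' Write an RDF as CSV
#' @param rdf an `"rdf"` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_rdf_csv <- function(rdf, path) {
  utils::write.csv(data.frame(r = rdf$r, g = rdf$g), path,
                   row.names = FALSE)
  invisible(path)
}

#' Serialize a fit report
#'
#' Parameters as CSV, diagnostics (singular values, rank, residual RMS,
#' CMD summary) as JSON next to it.
#'
#' @param fit an `"fm_fit"`
#' @param stem output path stem; writes `<stem>-params.csv` and
#'   `<stem>-diagnostics.json`
#' @return the two paths, invisibly
#' @export
write_fit_report <- function(fit, stem) {
  p <- coef(fit)
  csv <- paste0(stem, "-params.csv")
  utils::write.csv(data.frame(parameter = names(p), value = unname(p)),
                   csv, row.names = FALSE)
  js <- paste0(stem, "-diagnostics.json")
  diag <- list(
    n_frames = fit$n_frames,
    pass1 = if (!is.null(fit$pass1)) list(
      residual_rms = fit$pass1$residual_rms, rank = fit$pass1$rank,
      singular_values = fit$pass1$singular_values),
    cmd = if (!is.null(fit$cmd)) list(
      charges = as.list(fit$cmd$charges), lambda1 = fit$cmd$lambda1,
      eigenvalues = fit$cmd$eigenvalues,
      reconstruction_error = fit$cmd$reconstruction_error,
      anchor = fit$cmd$anchor),
    pass2 = list(residual_rms = fit$pass2$residual_rms,
                 rank = fit$pass2$rank, rcond = fit$pass2$rcond,
                 singular_values = fit$pass2$singular_values))
  jsonlite::write_json(diag, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, js))
}
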