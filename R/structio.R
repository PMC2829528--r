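#' @include AllClasses.R geometry.R
NULL

# split "path" or "path:CHAIN" into its parts; a trailing single-character
# component after the last ':' is the chain id.
parseSelector <- function(selector) {
  m <- regmatches(selector, regexec("^(.*):([A-Za-z0-9])$", selector))[[1]]
  if (length(m) == 3L && file.exists(m[2]) && !file.exists(selector))
    list(path = m[2], chain = m[3])
  else list(path = selector, chain = NULL)
}

#' Read a C-alpha backbone from a PDB file
#'
#' Parses the file with bio3d and keeps one coordinate triple per residue, in
#' file order: C-alpha atoms only, blank or 'A' altloc, first model of
#' multi-model files. Residues must be one of the 20 standard amino acids or
#' MSE (selenomethionine, renamed to MET); others are skipped with a warning.
#' Insertion codes and duplicate residue numbers are ignored: file order
#' rules.
#'
#' @param source path to a PDB file, optionally with a chain suffix as in
#'   \code{"file.pdb:A"} (an explicit \code{chain} argument wins).
#' @param chain optional single chain identifier; default uses all chains.
#' @param id label for the structure (default: file base name plus chain).
#' @return A [CaStructure-class].
#' @export
readStructure <- function(source, chain = NULL, id = NULL) {
  sel <- parseSelector(source)
  if (is.null(chain)) chain <- sel$chain
  path <- sel$path
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$elety == "CA" &
                 (is.na(atoms$alt) | atoms$alt %in% c("", "A")), ,
                 drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  mse <- atoms$resid == "MSE"
  atoms$resid[mse] <- "MET"
  bad <- !(atoms$resid %in% aaThree)
  if (any(bad)) {
    warning(sprintf("skipping %d non-standard residue(s) in %s: %s",
                    sum(bad), basename(path),
                    paste(unique(atoms$resid[bad]), collapse = ", ")))
    atoms <- atoms[!bad, , drop = FALSE]
  }
  if (nrow(atoms) == 0L)
    stop("no CA atoms", if (!is.null(chain)) paste0(" in chain ", chain),
         " in ", path)
  if (is.null(id)) {
    id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
    if (!is.null(chain)) id <- paste0(id, ":", chain)
  }
  caStructure(cbind(atoms$x, atoms$y, atoms$z), id = id,
              resid = atoms$resid, resno = atoms$resno)
}

#' Read several structures from selector strings
#'
#' @param selectors character vector of \code{"path"} or \code{"path:CHAIN"}
#'   selectors.
#' @return List of [CaStructure-class] objects.
#' @export
readStructures <- function(selectors) lapply(selectors, readStructure)

#' Write a transformed structure as a PDB file
#'
#' Applies the rigid transform \eqn{G = (H - e t) R} to the structure's
#' C-alpha coordinates and writes standard fixed-column ATOM records (three
#' decimal places), preserving residue count, order, names and numbers.
#'
#' @param structure a [CaStructure-class].
#' @param transform a [RigidTransform-class] (default identity).
#' @param file output path.
#' @return Invisibly, the output path.
#' @export
writeTransformedPdb <- function(structure, transform = identityTransform(),
                                file) {
  coords <- applyTransform(caCoords(structure), transform)
  bio3d::write.pdb(file = file, xyz = as.numeric(t(coords)),
                   resno = residueNumbers(structure),
                   resid = residueNames(structure),
                   elety = rep("CA", length(structure)),
                   chain = rep("A", length(structure)))
  invisible(file)
}

#' Write the consensus as a PDB-like pseudo-structure
#'
#' The consensus is geometric only — a sequence of pseudo C-alpha positions,
#' not a real protein — so it is written with residue name UNK.
#'
#' @param x a [MapsciAlignment-class], [Correspondence-class], or a plain
#'   coordinate matrix.
#' @param file output path.
#' @return Invisibly, the output path.
#' @export
writeConsensusPdb <- function(x, file) {
  coords <- if (is.matrix(x)) x else consensusCoords(x)
  if (nrow(coords) == 0L) stop("empty consensus")
  n <- nrow(coords)
  bio3d::write.pdb(file = file, xyz = as.numeric(t(coords)),
                   resno = seq_len(n), resid = rep("UNK", n),
                   elety = rep("CA", n), chain = rep("C", n))
  invisible(file)
}

# one-letter codes for a row of the correspondence
rowLetters <- function(idx, resid) {
  out <- rep("-", length(idx))
  hit <- !is.na(idx)
  letters1 <- suppressWarnings(bio3d::aa321(resid[idx[hit]]))
  letters1[is.na(letters1)] <- "X"
  out[hit] <- letters1
  out
}

#' Write a correspondence in NBRF/PIR format
#'
#' One PIR entry per protein (plus optionally the consensus, whose pseudo
#' residues print as 'X'): a \code{">P1;name"} header, a description line,
#' and the gapped sequence in 60-character lines terminated by \code{*}.
#' Gaps print as '-'; all sequences have the full alignment width.
#'
#' @param x a [MapsciAlignment-class], or a [Correspondence-class] together
#'   with \code{structures}.
#' @param file output path.
#' @param structures list of [CaStructure-class] objects supplying names and
#'   residue codes (taken from \code{x} when it is a result object).
#' @param includeConsensus write the consensus row too (default TRUE).
#' @return Invisibly, the output path.
#' @export
writePir <- function(x, file, structures = NULL, includeConsensus = TRUE) {
  H <- if (is(x, "MapsciAlignment")) x@correspondence else x
  if (is(x, "MapsciAlignment") && is.null(structures))
    structures <- x@structures
  if (is.null(structures))
    stop("structures are required to derive residue codes")
  idx <- H@index
  K <- nrow(idx) - 1L
  stopifnot(length(structures) == K)
  lines <- character(0)
  emit <- function(name, seqChars) {
    body <- paste0(seqChars, collapse = "")
    chunks <- substring(body, seq(1L, nchar(body), 60L),
                        pmin(seq(1L, nchar(body), 60L) + 59L, nchar(body)))
    chunks[length(chunks)] <- paste0(chunks[length(chunks)], "*")
    c(paste0(">P1;", name), "structural alignment", chunks)
  }
  if (includeConsensus) {
    consChars <- ifelse(is.na(idx[1L, ]), "-", "X")
    lines <- c(lines, emit("consensus", consChars))
  }
  for (j in seq_len(K))
    lines <- c(lines, emit(structureId(structures[[j]]),
                           rowLetters(idx[j + 1L, ],
                                      residueNames(structures[[j]]))))
  writeLines(lines, file)
  invisible(file)
}

#' Parse an NBRF/PIR alignment file
#'
#' @param file path to a PIR file as written by [writePir()].
#' @return Named character vector of gapped sequences (gaps as '-').
#' @export
readPir <- function(file) {
  lines <- readLines(file)
  heads <- grep("^>P1;", lines)
  if (!length(heads)) stop("no PIR entries in ", file)
  bounds <- c(heads, length(lines) + 1L)
  out <- character(length(heads))
  names(out) <- sub("^>P1;", "", lines[heads])
  for (i in seq_along(heads)) {
    body <- lines[(heads[i] + 2L):(bounds[i + 1L] - 1L)]
    s <- gsub("[[:space:]]", "", paste0(body, collapse = ""))
    if (!grepl("\\*$", s)) stop("PIR entry not terminated by '*'")
    out[i] <- sub("\\*$", "", s)
  }
  widths <- nchar(out)
  if (length(unique(widths)) != 1L)
    stop("PIR rows have unequal widths: ", paste(widths, collapse = ", "))
  out
}

#' Write all outputs of a multiple alignment to a directory
#'
#' Writes one transformed PDB per input structure, the consensus as a
#' PDB-like pseudo-structure, the alignment in NBRF/PIR format, and a JSON
#' report with the SC-distance trace and strict-core statistics.
#'
#' @param result a [MapsciAlignment-class].
#' @param dir output directory (created if needed).
#' @param cutoff strict-core cutoff in Angstrom for the report.
#' @return Invisibly, the report as a list.
#' @export
exportAlignment <- function(result, dir, cutoff = 4.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(result@structures)) {
    s <- result@structures[[j]]
    writeTransformedPdb(s, result@transforms[[j]],
                        file.path(dir, paste0(structureId(s), "_aligned.pdb")))
  }
  writeConsensusPdb(result, file.path(dir, "consensus.pdb"))
  writePir(result, file.path(dir, "alignment.pir"))
  rep <- coreReport(result, cutoff)
  report <- list(sc_trace = result@scTrace,
                 iterations = result@iterations,
                 initial_consensus = structureId(
                   result@structures[[result@initialIndex]]),
                 strategy = result@strategy,
                 core_size = rep$core_size,
                 core_percent = rep$core_percent,
                 core_rmsd = rep$core_rmsd,
                 core_columns = rep$core_columns)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
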