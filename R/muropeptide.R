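.WATER <- c(H = 2L, O = 1L)
.H2 <- c(H = 2L)

#' Residue library for muropeptide assembly
#'
#' Free-molecule elemental formulas of the residues occurring in the Tri->KR
#' muropeptide: the glycan sugars GlcNAc and MurNAc, the stem-peptide amino
#' acids Ala, iGlu (D-isoglutamate) and DAP (meso-diaminopimelate), and the
#' Lys-Arg remnant of trypsin-digested Lpp. Every condensation bond formed
#' on assembly (peptide, isopeptide, glycosidic or lactyl-amide) removes one
#' water from the sum of free-molecule formulas.
#'
#' @param file Optional path to a CSV with columns `name,formula` overriding
#'   the built-in library (the built-in table ships at
#'   `system.file("extdata", "residue_library.csv", package = "lppkin")`).
#' @return Named list of [composition()] objects.
#' @examples
#' lib <- residue_library()
#' monoisotopic_mass(lib$Arg) # 174.11 at 2 dp
#' @export
residue_library <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "residue_library.csv", package = "lppkin")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula") %in% names(tab)))
  if (anyDuplicated(tab$name)) stop("duplicate residue names in library")
  out <- lapply(tab$formula, parse_formula)
  names(out) <- tab$name
  out
}

lookup_residue <- function(name, library) {
  if (!name %in% names(library))
    stop("unknown residue: ", name, call. = FALSE)
  library[[name]]
}

#' Define a muropeptide as a branched residue assembly
#'
#' A muropeptide spec is an ordered residue list with the number of
#' condensation bonds, a reduction flag (MurNAc reduced to muramitol during
#' sample work-up, +2 H), and a moiety tag per residue. Moieties are the
#' independently labelable units of the pulse-chase design: the
#' disaccharide-tripeptide stem (`"stem"`) and the Lys-Arg remnant of Lpp
#' (`"lpp"`). For a single covalently fused assembly of n residues the bond
#' count is n - 1.
#'
#' @param residues Character vector of residue names.
#' @param moieties Character vector, one moiety tag per residue.
#' @param n_bonds Number of condensation bonds (default `length(residues) - 1`,
#'   a single fused assembly).
#' @param reduced Logical; MurNAc reduced to muramitol.
#' @param name Optional display name.
#' @return Object of class `muropeptide`.
#' @export
muropeptide <- function(residues, moieties, n_bonds = length(residues) - 1L,
                        reduced = FALSE, name = NULL) {
  stopifnot(length(residues) >= 1, length(moieties) == length(residues),
            n_bonds >= 0)
  structure(
    list(residues = as.character(residues), moieties = as.character(moieties),
         n_bonds = as.integer(n_bonds), reduced = isTRUE(reduced),
         name = name %||% paste(residues, collapse = "-")),
    class = "muropeptide")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.muropeptide <- function(x, ...) {
  cat("<muropeptide> ", x$name, ": ", length(x$residues), " residues, ",
      x$n_bonds, " bonds", if (x$reduced) ", reduced", "\n", sep = "")
  invisible(x)
}

#' The Tri->KR parental muropeptide
#'
#' GlcNAc-MurNAc(reduced)-L-Ala-D-iGlu-DAP cross-linked through the DAP side
#' chain to the L-Lys-L-Arg dipeptide that trypsin digestion leaves of the
#' Lpp C-terminus: 7 residues, 6 condensation bonds, one fused assembly.
#' Moiety partition: the disaccharide-tripeptide is `"stem"`, Lys-Arg is
#' `"lpp"`.
#'
#' @return A [muropeptide()].
#' @export
tri_kr <- function() {
  muropeptide(
    residues = c("GlcNAc", "MurNAc", "Ala", "iGlu", "DAP", "Lys", "Arg"),
    moieties = c(rep("stem", 5), rep("lpp", 2)),
    n_bonds = 6L, reduced = TRUE,
    name = "GlcNAc-MurNAc(r)-Ala-iGlu-DAP->Lys-Arg")
}

#' Assemble the elemental composition of a muropeptide
#'
#' Sum of free-molecule residue compositions minus one water per
#' condensation bond, plus H2 if the MurNAc is reduced. A negative element
#' count signals an inconsistent spec (more bonds than the atoms allow).
#'
#' @param spec A [muropeptide()].
#' @param library Residue library, see [residue_library()].
#' @return A [composition()].
#' @examples
#' assemble_composition(tri_kr()) # C46H82N12O22, 1154.57 Da at 2 dp
#' @export
assemble_composition <- function(spec, library = residue_library()) {
  comp <- Reduce(comp_add, lapply(spec$residues, lookup_residue, library))
  comp <- comp_subtract(comp, comp_scale(composition(H = 2, O = 1), spec$n_bonds))
  if (spec$reduced) comp <- comp_add(comp, composition(H = 2))
  comp
}

#' Label states of a two-moiety muropeptide
#'
#' A label state assigns `"light"` (newly synthesized, 12C/14N) or `"heavy"`
#' (pre-existing, 13C/15N) to each moiety. The four Tri->KR isotopologues,
#' named stem-age -> lpp-age, are: `nn` = new->new (all light),
#' `oo` = old->old (all heavy), `on` = old->new (heavy stem, light lpp),
#' `no` = new->old (light stem, heavy lpp).
#'
#' @param stem,lpp `"light"` or `"heavy"`.
#' @return Named character vector (a label state).
#' @export
label_state <- function(stem = "light", lpp = "light") {
  stopifnot(stem %in% c("light", "heavy"), lpp %in% c("light", "heavy"))
  c(stem = stem, lpp = lpp)
}

#' @return `isotopologue_states()`: the four label states in fixed column
#'   order nn, no, on, oo (matching the published table layout).
#' @rdname label_state
#' @export
isotopologue_states <- function() {
  list(nn = label_state("light", "light"),
       no = label_state("light", "heavy"),
       on = label_state("heavy", "light"),
       oo = label_state("heavy", "heavy"))
}

#' Neutral monoisotopic mass of a labeled muropeptide
#'
#' Light assembled mass plus, for each heavy moiety, the 13C/15N shift of
#' that moiety's residues. Water losses carry no C or N, so the moiety shift
#' uses the residue C/N sums only and the moiety masses are exactly
#' additive: m(hybrid A) + m(hybrid B) = m(all light) + m(all heavy).
#'
#' @param spec A [muropeptide()].
#' @param labels A [label_state()] covering `unique(spec$moieties)`.
#' @param library Residue library.
#' @return Mass in Da.
#' @examples
#' isotopologue_mass(tri_kr(), label_state("heavy", "heavy")) # 1212.69
#' @export
isotopologue_mass <- function(spec, labels, library = residue_library()) {
  tags <- unique(spec$moieties)
  if (!setequal(names(labels), tags))
    stop("label state covers {", paste(names(labels), collapse = ","),
         "} but spec has moieties {", paste(tags, collapse = ","), "}")
  mass <- monoisotopic_mass(assemble_composition(spec, library))
  for (tag in tags) {
    if (labels[[tag]] == "heavy") {
      comp <- Reduce(comp_add,
                     lapply(spec$residues[spec$moieties == tag],
                            lookup_residue, library))
      mass <- mass + heavy_shift(comp)
    }
  }
  mass
}

#' MS2 fragment ladder of the Tri->KR muropeptide
#'
#' The seven-species ladder observed on fragmentation of the parental ion:
#' sequential losses of GlcNAc, MurNAc(r), Ala, iGlu and DAP from the stem
#' end, then Lys, down to free Arg. Each fragment is bookkept as a standard
#' condensation product (hydrolytic cleavage), inheriting its residues'
#' moiety tags from the parent.
#'
#' @param spec Parental [muropeptide()]; must be the Tri->KR assembly.
#' @return Named list of 7 [muropeptide()] specs, parental first.
#' @export
fragment_series <- function(spec = tri_kr()) {
  parent <- tri_kr()
  if (!identical(spec$residues, parent$residues) ||
      !identical(spec$moieties, parent$moieties) || !spec$reduced)
    stop("fragment_series() supports the Tri->KR parental spec")
  keep <- list(
    "GlcNAc-MurNAc(r)-Ala-iGlu-DAP->Lys-Arg" = 1:7,
    "MurNAc(r)-Ala-iGlu-DAP->Lys-Arg"        = 2:7,
    "Ala-iGlu-DAP->Lys-Arg"                  = 3:7,
    "iGlu-DAP->Lys-Arg"                      = 4:7,
    "DAP->Lys-Arg"                           = 5:7,
    "Lys-Arg"                                = 6:7,
    "Arg"                                    = 7)
  out <- lapply(seq_along(keep), function(i) {
    idx <- keep[[i]]
    muropeptide(spec$residues[idx], spec$moieties[idx],
                n_bonds = length(idx) - 1L,
                reduced = "MurNAc" %in% spec$residues[idx],
                name = names(keep)[i])
  })
  names(out) <- names(keep)
  out
}

#' Theoretical isotopologue mass grid of the Tri->KR fragment ladder
#'
#' 7 fragments x 4 label states of neutral monoisotopic masses. Column
#' order is nn (all light), no (heavy lpp), on (heavy stem), oo (all heavy);
#' fragments that contain no stem residue (Lys-Arg, Arg) repeat their light
#' mass in the heavy-stem columns.
#'
#' @param spec Parental [muropeptide()].
#' @param library Residue library.
#' @param digits If non-NULL, round half-up to this many decimals.
#' @return 7 x 4 numeric matrix with fragment names as rownames and
#'   isotopologue codes as colnames.
#' @examples
#' theoretical_table(digits = 2)
#' @export
theoretical_table <- function(spec = tri_kr(), library = residue_library(),
                              digits = NULL) {
  frags <- fragment_series(spec)
  states <- isotopologue_states()
  out <- sapply(states, function(st)
    sapply(frags, function(fr) {
      st_use <- st[unique(fr$moieties)]
      isotopologue_mass(fr, st_use, library)
    }))
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Long-format view of the theoretical table
#'
#' @inheritParams theoretical_table
#' @return data.frame with columns fragment, isotopologue, mass.
#' @export
theoretical_masses <- function(spec = tri_kr(), library = residue_library()) {
  tab <- theoretical_table(spec, library)
  data.frame(
    fragment = rep(rownames(tab), times = ncol(tab)),
    fragment_index = rep(seq_len(nrow(tab)), times = ncol(tab)),
    isotopologue = rep(colnames(tab), each = nrow(tab)),
    mass = as.vector(tab),
    stringsAsFactors = FALSE)
}
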