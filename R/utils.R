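# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "allopath_error") {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

validation_error <- function(fmt, ...) {
  stopf(fmt, ..., class = "allopath_validation_error")
}

format_error <- function(fmt, ...) {
  stopf(fmt, ..., class = "allopath_format_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard atomic masses (a.m.u.) for elements that occur in protein /
# glycan / small-ligand systems. Unknown elements fall back to carbon.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  "NA" = 22.990, CL = 35.45, K = 39.098, CA = 40.078, BR = 79.904,
  F = 18.998, I = 126.904
)

element_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

# Infer element from a PDB atom name when columns 77-78 are absent:
# strip leading digits (e.g. "1HB" -> H), then take the leading letters;
# two-letter elements are only trusted when they match a known symbol.
infer_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  nm <- sub("^[0-9']+", "", nm)
  letters_only <- sub("[^A-Z].*$", "", nm)
  two <- substr(letters_only, 1, 2)
  one <- substr(letters_only, 1, 1)
  ifelse(two %in% names(.atomic_masses) & !(one %in% c("C", "N", "O", "H", "S", "P")),
         two, one)
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) validation_error("coordinates must be an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}
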