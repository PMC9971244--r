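# Bundled flavonoid reference data: the nine-compound training table, the
# 26-compound screening (ranking) table, and curated structures for all 26
# named compounds. Values are transcribed digit-for-digit from the published
# tables; loaders verify a checksum against the shipped copy.

.fixture_md5 <- c(
  flavonoid_training.csv   = "04570b776b11cae8c18a15f52f14063d",
  flavonoid_screening.csv  = "cb339c80566f6337c139b73fcb8ca7e7",
  flavonoid_structures.csv = "f4fa200da3dc72be5a410b9899854367"
)

.fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "molactivity")
  if (!nzchar(path)) {
    stop_molactivity("corrupted_fixture_error",
                     sprintf("bundled fixture '%s' not found", file))
  }
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[file]]))) {
    stop_molactivity("corrupted_fixture_error",
                     sprintf("fixture '%s' fails its checksum (%s)", file, md5))
  }
  path
}

#' Training table: nine flavonoids with observed IC50
#'
#' The descriptor pair `(D, zeta)` and observed anti-tyrosinase IC50 (uM)
#' for nine flavonoids isolated from a single plant source; the data the
#' nine-coefficient model is fitted to.
#'
#' @return data frame with columns `name`, `D`, `zeta`, `ic50` (9 rows).
#' @export
load_training_table <- function() {
  utils::read.csv(.fixture_path("flavonoid_training.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Screening table: 26 compounds in tabulated rank order
#'
#' The reference virtual-screening result: 26 compounds with their
#' tabulated descriptor pairs and predicted IC50, in rank order
#' (strongest inhibitor first). Note the tabulated predictions are
#' internally inconsistent with the published coefficients; see the
#' methods vignette.
#'
#' @return data frame with columns `rank`, `name`, `D`, `zeta`,
#'   `ic50_predicted` (26 rows).
#' @export
load_screening_table <- function() {
  utils::read.csv(.fixture_path("flavonoid_screening.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Curated structures for the 26 screening compounds
#'
#' SMILES for the standard published structure of each named compound,
#' with per-compound flags recording whether the tabulated `D` and `zeta`
#' are reproducible from that structure. Irreproducible entries are
#' transcription or hand-calculation slips in the reference tables (e.g.
#' tabulated external sums that are odd, which no graph can produce since
#' the external numerator is twice a sum of pair distances); each carries
#' an explanatory note.
#'
#' @return data frame with columns `name`, `smiles`, `n_heavy`,
#'   `d_reproducible`, `zeta_reproducible`, `note` (26 rows).
#' @export
load_structures <- function() {
  utils::read.csv(.fixture_path("flavonoid_structures.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Path to the bundled SMILES file of the screening compounds
#'
#' @return path to a `.smi` file (`SMILES<TAB>name`, 26 records) suitable
#'   as input to [read_smi_graphs()] or the command-line interface.
#' @export
structures_smi_path <- function() {
  system.file("extdata", "flavonoid_structures.smi", package = "molactivity")
}
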