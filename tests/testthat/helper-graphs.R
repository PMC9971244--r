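# Shared fixtures and helpers, built in code at test time.

structure_smiles <- function(name) {
  st <- load_structures()
  st$smiles[match(name, st$name)]
}

taxifolin_graph <- function() {
  graph_from_smiles(structure_smiles("Taxfolin"), name = "taxifolin")
}

# Closed forms for parametric families under the distinct-degree-values
# irregularity reading (derived by hand; see the methods vignette).
star_D <- function(k) 2 * k * (k - 1) / (k + 1)^3
star_zeta <- function(k) (1 / k) / (k + 1)^2
cycle_zeta <- function(n) (n %/% 2) / (2 * n)

# Run the installed CLI in a child process; returns list(status, stdout, stderr).
run_cli <- function(args) {
  script <- system.file("cli", "molactivity.R", package = "molactivity")
  out <- tempfile(); err <- tempfile()
  status <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(script, args),
    stdout = out, stderr = err,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = status,
       stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
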