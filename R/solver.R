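# Linear-program interface. No LP solver ships with the R stack used here,
# so problems are batched to a small Python helper using scipy's HiGHS
# backend (deterministic). Each problem is a list with elements
#   c, sense ("max"/"min"), lb, ub,
#   A_eq/b_eq and optionally A_ub/b_ub, matrices as COO triplet lists
#   (i, j, x, nrow, ncol; 1-based).

find_python <- function() {
  cand <- Sys.getenv("MINTNET_PYTHON", "")
  if (nzchar(cand)) return(cand)
  for (p in c("python", "python3")) {
    path <- Sys.which(p)
    if (nzchar(path)) return(path)
  }
  mn_stop("no python interpreter found; the flux module needs python + scipy ",
          "(set MINTNET_PYTHON to override)")
}

as_triplets <- function(i, j, x, nrow, ncol) {
  list(i = as.integer(i), j = as.integer(j), x = as.numeric(x),
       nrow = as.integer(nrow), ncol = as.integer(ncol))
}

#' Solve a batch of linear programs
#'
#' @param problems List of LP specifications (see `R/solver.R`).
#' @return List of results: `status`, and for optimal solutions `objective`
#'   and `x`.
#' @keywords internal
solve_lp_batch <- function(problems) {
  if (length(problems) == 0) return(list())
  script <- system.file("python", "lp_solve.py", package = "mintnet")
  if (!nzchar(script)) mn_stop("lp_solve.py not found in installed package")
  fin <- tempfile("lp_in_", fileext = ".json")
  fout <- tempfile("lp_out_", fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(list(problems = problems), fin,
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(find_python(), c(script, fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    mn_stop("LP solver failed: ", paste(status, collapse = "\n"))
  }
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
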