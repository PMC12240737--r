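# Generics and simple accessors.

#' @rdname codec-api
#' @param codec a codec object.
#' @export
setGeneric("codecDim", function(codec) standardGeneric("codecDim"))

#' @rdname codec-api
#' @export
setGeneric("codecBounds", function(codec) standardGeneric("codecBounds"))

#' Codec API: encode, decode, canonicalize
#'
#' `encodeMolecule` maps a SMILES to its latent vector; `decodeVector` maps
#' a latent vector back to a SMILES (or `NA` on decode failure);
#' `canonicalizeInput` is the codec's notion of a canonical identifier
#' (chemical canonicalization for molecular codecs, numeric reformatting
#' for the coordinate codec). `codecDim`/`codecBounds` expose the latent
#' dimension and clamping bounds.
#'
#' @param codec a codec object.
#' @param smiles a SMILES string (or coordinate string for
#'   [IdentityCodec-class]).
#' @param z numeric latent vector of length `codecDim(codec)`.
#' @param s identifier string to canonicalize; `NA` if invalid.
#' @name codec-api
#' @export
setGeneric("encodeMolecule",
           function(codec, smiles) standardGeneric("encodeMolecule"))

#' @rdname codec-api
#' @export
setGeneric("decodeVector", function(codec, z) standardGeneric("decodeVector"))

#' @rdname codec-api
#' @export
setGeneric("canonicalizeInput",
           function(codec, s) standardGeneric("canonicalizeInput"))

#' @rdname ProblemDefinition-class
#' @param problem a [ProblemDefinition-class].
#' @export
setGeneric("objectives", function(problem) standardGeneric("objectives"))

#' @rdname ProblemDefinition-class
#' @export
setGeneric("constraints", function(problem) standardGeneric("constraints"))

#' @rdname MoleculePopulation-class
#' @param pop a [MoleculePopulation-class].
#' @export
setGeneric("populationSize", function(pop) standardGeneric("populationSize"))

#' @rdname MoleculePopulation-class
#' @export
setGeneric("moleculeSmiles", function(pop) standardGeneric("moleculeSmiles"))

#' @rdname MoleculePopulation-class
#' @export
setGeneric("latentVectors", function(pop) standardGeneric("latentVectors"))

#' @rdname MoleculePopulation-class
#' @export
setGeneric("objectiveValues", function(pop) standardGeneric("objectiveValues"))

#' @rdname MoleculePopulation-class
#' @export
setGeneric("sigmaValues", function(pop) standardGeneric("sigmaValues"))

#' @rdname MoleculePopulation-class
#' @export
setGeneric("cvDegrees", function(pop) standardGeneric("cvDegrees"))

#' @rdname MoleculePopulation-class
#' @export
setGeneric("rankingTable", function(pop) standardGeneric("rankingTable"))

# ---- methods ---------------------------------------------------------------

#' @rdname codec-api
setMethod("codecDim", "MolecularCodec", function(codec) codec@dim)

#' @rdname codec-api
setMethod("codecBounds", "MolecularCodec", function(codec) {
  if (nrow(codec@bounds) == 0L) NULL else codec@bounds
})

#' @rdname ProblemDefinition-class
setMethod("objectives", "ProblemDefinition", function(problem)
  problem@objectives)

#' @rdname ProblemDefinition-class
setMethod("constraints", "ProblemDefinition", function(problem)
  problem@constraints)

#' Number and names of objectives/constraints
#'
#' @param problem a [ProblemDefinition-class].
#' @return counts or name vectors.
#' @export
nObjectives <- function(problem) length(problem@objectives)

#' @rdname nObjectives
#' @export
nConstraints <- function(problem) length(problem@constraints)

#' @rdname nObjectives
#' @export
objectiveNames <- function(problem)
  vapply(problem@objectives, slot, character(1), "name")

#' @rdname nObjectives
#' @export
constraintNames <- function(problem)
  vapply(problem@constraints, slot, character(1), "name")

#' @rdname MoleculePopulation-class
setMethod("populationSize", "MoleculePopulation", function(pop)
  length(pop@smiles))

#' @rdname MoleculePopulation-class
setMethod("moleculeSmiles", "MoleculePopulation", function(pop) pop@smiles)

#' @rdname MoleculePopulation-class
setMethod("latentVectors", "MoleculePopulation", function(pop) pop@latent)

#' @rdname MoleculePopulation-class
setMethod("objectiveValues", "MoleculePopulation", function(pop)
  pop@objectives)

#' @rdname MoleculePopulation-class
setMethod("sigmaValues", "MoleculePopulation", function(pop) pop@sigmas)

#' @rdname MoleculePopulation-class
setMethod("cvDegrees", "MoleculePopulation", function(pop) pop@cv)

#' @rdname MoleculePopulation-class
setMethod("rankingTable", "MoleculePopulation", function(pop) pop@ranking)

setMethod("show", "ProblemDefinition", function(object) {
  cat("ProblemDefinition:", length(object@objectives), "objective(s) [",
      paste(objectiveNames(object), collapse = ", "), "],",
      length(object@constraints), "constraint(s) [",
      paste(constraintNames(object), collapse = ", "), "]\n")
})

setMethod("show", "TableCodec", function(object) {
  cat(sprintf("TableCodec: %d entries, dim %d\n",
              length(object@smiles), object@dim))
})

setMethod("show", "MoleculePopulation", function(object) {
  n <- length(object@smiles)
  cat(sprintf("MoleculePopulation: %d molecule(s), %d objective(s), %d constraint(s)\n",
              n, ncol(object@objectives), ncol(object@sigmas)))
  if (n && ncol(object@sigmas))
    cat(sprintf("  feasible: %d/%d\n",
                sum(rowSums(object@sigmas > 0) == 0L), n))
})

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf("OptimizationResult: final population %d, feasible %d, %d logged generation(s)\n",
              populationSize(object@finalPopulation),
              nrow(object@feasible), nrow(object@log)))
})
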