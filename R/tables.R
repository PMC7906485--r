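# Planted bicluster designs used by the two shipped simulation fixtures.
# Subjects are 1-based row indices; components are 1-based column indices.

# 400 x 10 design: four blocks of (38, 35, 37, 40) subjects over three
# components each; subject and component overlaps between blocks are allowed.
.sim1Design <- list(
  list(subjects = c(278, 342, 118, 261, 12, 378, 313, 331, 295, 318, 163, 53,
                    64, 327, 133, 218, 330, 380, 185, 28, 209, 79, 120, 391,
                    67, 311, 137, 190, 41, 25, 345, 29, 354, 158, 177, 141,
                    13, 291),
       components = c(2, 9, 3)),
  list(subjects = c(271, 195, 325, 31, 12, 174, 58, 324, 1, 39, 169, 95, 383,
                    149, 197, 108, 231, 209, 392, 265, 339, 35, 170, 17, 241,
                    293, 274, 25, 27, 123, 140, 291, 43, 101, 176),
       components = c(1, 4, 5)),
  list(subjects = c(125, 367, 264, 71, 259, 15, 314, 1, 154, 269, 16, 174, 70,
                    234, 77, 145, 353, 10, 273, 114, 329, 118, 157, 381, 335,
                    357, 374, 52, 140, 286, 251, 334, 89, 128, 88, 12, 237),
       components = c(6, 7, 8)),
  list(subjects = c(46, 29, 233, 5, 338, 27, 194, 65, 169, 346, 263, 385, 159,
                    165, 312, 361, 268, 69, 128, 109, 93, 281, 124, 390, 345,
                    248, 352, 123, 251, 254, 121, 234, 44, 320, 351, 260, 23,
                    376, 24, 100),
       components = c(2, 4, 6)))

# 40 x 10 design: three disjoint 13-subject blocks (subject 37 unassigned)
# over disjoint component triples (component 10 unused).
.sim2Design <- list(
  list(subjects = c(1, 2, 3, 4, 6, 7, 21, 27, 29, 31, 35, 38, 40),
       components = c(1, 8, 3)),
  list(subjects = c(5, 13, 17, 18, 19, 20, 23, 24, 26, 28, 30, 33, 34),
       components = c(2, 4, 5)),
  list(subjects = c(8, 9, 10, 11, 12, 14, 15, 16, 22, 25, 32, 36, 39),
       components = c(6, 7, 9)))

.designToSet <- function(design) {
  BiclusterSet(lapply(design, function(d)
    Bicluster(as.character(d$subjects), paste0("C", d$components))))
}

#' Planted ground truth of the 400 x 10 simulation design
#'
#' Four biclusters of 38, 35, 37 and 40 subjects over the component triples
#' C2/C9/C3, C1/C4/C5, C6/C7/C8 and C2/C4/C6; blocks share some subjects and
#' components. Used by [sim1Fixture()] and the sorting-method comparison.
#'
#' @return a [BiclusterSet-class] of 4 biclusters.
#' @export
sim1Truth <- function() .designToSet(.sim1Design)

#' Planted ground truth of the 40 x 10 simulation design
#'
#' Three disjoint biclusters of 13 subjects each over the disjoint component
#' triples C1/C8/C3, C2/C4/C5 and C6/C7/C9 (subject 37 and component C10
#' belong to no block). Used by [sim2Fixture()] for end-to-end recovery
#' checks.
#'
#' @return a [BiclusterSet-class] of 3 biclusters.
#' @export
sim2Truth <- function() .designToSet(.sim2Design)
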