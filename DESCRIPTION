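Package: pathclip
Title: Implicit-Function Boolean Combination of Plane-Widget Clipping
    Paths for Surgical Model Clipping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns an ordered chain of connected plane widgets (a surgical
    clipping path) into a single signed implicit function by recursive
    Boolean combination, where union is the pointwise minimum and
    intersection the pointwise maximum of plane signed values.  The chain
    is reduced to a 2D polyline on a transection plane and the polyline's
    segment/ray intersection pattern decides which Boolean operation joins
    each sub-chain.  The resulting scalar field clips triangle surface
    meshes into parts, optionally limited in depth by a thickness plane
    for tumour-removal style planning.  Includes instrumentation of the
    recursion cost with its best-, worst- and average-case laws, synthetic
    mesh and path generators, STL/OBJ/PLY readers and writers, a JSON
    clipping-path schema, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
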