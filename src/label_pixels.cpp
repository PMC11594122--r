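#include <Rcpp.h>
using namespace Rcpp;

// Point-in-ring test, boundary inclusive. Ring is an n x 2 matrix of vertices,
// not closed (last vertex != first). Even-odd ray casting with an explicit
// on-segment check so that points lying exactly on an edge count as inside.
static bool point_in_ring(double px, double py, const NumericMatrix &ring) {
    int n = ring.nrow();
    bool inside = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
        double xi = ring(i, 0), yi = ring(i, 1);
        double xj = ring(j, 0), yj = ring(j, 1);
        // on-segment: collinear and within bounding box of the edge
        double cross = (xj - xi) * (py - yi) - (yj - yi) * (px - xi);
        if (cross == 0.0 &&
            px >= std::min(xi, xj) && px <= std::max(xi, xj) &&
            py >= std::min(yi, yj) && py <= std::max(yi, yj)) {
            return true;
        }
        if ((yi > py) != (yj > py)) {
            double xint = xi + (py - yi) / (yj - yi) * (xj - xi);
            if (px < xint) inside = !inside;
        }
    }
    return inside;
}

// geom: list of parts; each part: list of rings (first exterior, rest holes)
static bool point_in_geometry(double px, double py, const List &geom) {
    int nparts = geom.size();
    for (int p = 0; p < nparts; p++) {
        List part = geom[p];
        NumericMatrix outer = part[0];
        if (!point_in_ring(px, py, outer)) continue;
        bool in_hole = false;
        int nr = part.size();
        for (int h = 1; h < nr; h++) {
            NumericMatrix hole = part[h];
            if (point_in_ring(px, py, hole)) { in_hole = true; break; }
        }
        if (!in_hole) return true;
    }
    return false;
}

// Label every pixel of an nrow x ncol grid with the 1-based index of the first
// geometry (in the given order) whose polygon contains the pixel centre; 0 if
// none. Geometries must be supplied pre-sorted (callers sort by tract id so
// that boundary ties resolve to the lexicographically smallest id). transform
// is the affine c(a, b, c, d, e, f): x = c + a*(col+.5) + b*(row+.5),
// y = f + d*(col+.5) + e*(row+.5), with 0-based col/row. bboxes is a 4-column
// matrix (xmin, ymin, xmax, ymax) per geometry used to restrict the scan when
// the transform is axis-aligned (b == d == 0).
// [[Rcpp::export]]
IntegerMatrix label_pixels_cpp(int nrow, int ncol, NumericVector transform,
                               List geoms, NumericMatrix bboxes) {
    double a = transform[0], b = transform[1], c = transform[2];
    double d = transform[3], e = transform[4], f = transform[5];
    IntegerMatrix label(nrow, ncol);
    bool north_up = (b == 0.0 && d == 0.0);
    int ng = geoms.size();
    for (int g = 0; g < ng; g++) {
        List geom = geoms[g];
        int c0 = 0, c1 = ncol - 1, r0 = 0, r1 = nrow - 1;
        if (north_up) {
            double xmin = bboxes(g, 0), ymin = bboxes(g, 1);
            double xmax = bboxes(g, 2), ymax = bboxes(g, 3);
            // invert x = c + a*(col+.5) etc.; a > 0, e < 0 in the usual case
            double ca = (xmin - c) / a - 0.5, cb = (xmax - c) / a - 0.5;
            double ra = (ymax - f) / e - 0.5, rb = (ymin - f) / e - 0.5;
            c0 = std::max(0, (int)std::floor(std::min(ca, cb)));
            c1 = std::min(ncol - 1, (int)std::ceil(std::max(ca, cb)));
            r0 = std::max(0, (int)std::floor(std::min(ra, rb)));
            r1 = std::min(nrow - 1, (int)std::ceil(std::max(ra, rb)));
            if (c0 > c1 || r0 > r1) continue;
        }
        for (int row = r0; row <= r1; row++) {
            for (int col = c0; col <= c1; col++) {
                if (label(row, col) != 0) continue;
                double px = c + a * (col + 0.5) + b * (row + 0.5);
                double py = f + d * (col + 0.5) + e * (row + 0.5);
                if (point_in_geometry(px, py, geom)) label(row, col) = g + 1;
            }
        }
    }
    return label;
}

// [[Rcpp::export]]
LogicalVector points_in_geometry_cpp(NumericVector x, NumericVector y,
                                     List geom) {
    int n = x.size();
    LogicalVector out(n);
    for (int i = 0; i < n; i++)
        out[i] = point_in_geometry(x[i], y[i], geom);
    return out;
}
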