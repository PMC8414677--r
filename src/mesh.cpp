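#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D array (column-major, dims d).
// sigma is in voxel units, one value per axis; sigma <= 0 skips an axis.
// [[Rcpp::export(name = ".cppGaussianSmooth3D")]]
NumericVector cppGaussianSmooth3D(NumericVector field, IntegerVector dim,
                                  NumericVector sigma) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<double> buf(field.begin(), field.end());
  std::vector<double> out(buf.size());

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int radius = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * radius + 1);
    double sum = 0.0;
    for (int t = -radius; t <= radius; ++t) {
      k[t + radius] = std::exp(-0.5 * (double)t * t / (s * s));
      sum += k[t + radius];
    }
    for (double &w : k) w /= sum;

    const int n = (axis == 0) ? d1 : (axis == 1) ? d2 : d3;
    const R_xlen_t stride = (axis == 0) ? 1
                          : (axis == 1) ? (R_xlen_t)d1
                          : (R_xlen_t)d1 * d2;
    // iterate over all lines along `axis`
    for (int k3 = 0; k3 < (axis == 2 ? 1 : d3); ++k3) {
      for (int k2 = 0; k2 < (axis == 1 ? 1 : d2); ++k2) {
        for (int k1 = 0; k1 < (axis == 0 ? 1 : d1); ++k1) {
          R_xlen_t base;
          if (axis == 0)      base = (R_xlen_t)d1 * (k2 + (R_xlen_t)d2 * k3);
          else if (axis == 1) base = k1 + (R_xlen_t)d1 * d2 * k3;
          else                base = k1 + (R_xlen_t)d1 * k2;
          for (int i = 0; i < n; ++i) {
            double acc = 0.0;
            for (int t = -radius; t <= radius; ++t) {
              int j = i + t;
              if (j < 0 || j >= n) continue;  // zero boundary
              acc += k[t + radius] * buf[base + (R_xlen_t)j * stride];
            }
            out[base + (R_xlen_t)i * stride] = acc;
          }
        }
      }
    }
    std::swap(buf, out);
  }
  NumericVector res(buf.begin(), buf.end());
  res.attr("dim") = dim;
  return res;
}

// Kuhn 6-tetrahedron decomposition of the unit cube around diagonal 0-6.
// Cube corner offsets in (i, j, k):
static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

// Marching tetrahedra isosurface of a 3D scalar field at `level`.
// Vertices are interpolated along grid edges in physical coordinates
// (origin + index * spacing) and deduplicated by global edge id, so the
// resulting indexed mesh is watertight: every undirected edge is shared
// by exactly two triangles (field must be below level on the boundary
// layer, which the caller ensures by padding).
// [[Rcpp::export(name = ".cppMarchingTetrahedra")]]
List cppMarchingTetrahedra(NumericVector field, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           double level) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double *f = field.begin();
  const R_xlen_t ngrid = (R_xlen_t)d1 * d2 * d3;

  std::unordered_map<uint64_t, int> edge2vid;
  std::vector<double> verts;       // x,y,z triples
  std::vector<int> tris;           // 1-based triples

  auto gid = [&](int i, int j, int k) -> R_xlen_t {
    return i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
  };

  auto vertexOnEdge = [&](R_xlen_t a, R_xlen_t b) -> int {
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)ngrid + (uint64_t)b;
    auto it = edge2vid.find(key);
    if (it != edge2vid.end()) return it->second;
    double va = f[a], vb = f[b];
    double t = (level - va) / (vb - va);
    // decode grid indices
    int ai = (int)(a % d1), aj = (int)((a / d1) % d2), ak = (int)(a / ((R_xlen_t)d1 * d2));
    int bi = (int)(b % d1), bj = (int)((b / d1) % d2), bk = (int)(b / ((R_xlen_t)d1 * d2));
    double px = origin[0] + (ai + t * (bi - ai)) * spacing[0];
    double py = origin[1] + (aj + t * (bj - aj)) * spacing[1];
    double pz = origin[2] + (ak + t * (bk - ak)) * spacing[2];
    int id = (int)(verts.size() / 3) + 1;  // 1-based
    verts.push_back(px); verts.push_back(py); verts.push_back(pz);
    edge2vid.emplace(key, id);
    return id;
  };

  R_xlen_t corner[8];
  double val[8];

  for (int k = 0; k < d3 - 1; ++k) {
    for (int j = 0; j < d2 - 1; ++j) {
      for (int i = 0; i < d1 - 1; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          corner[c] = gid(i + CUBE[c][0], j + CUBE[c][1], k + CUBE[c][2]);
          val[c] = f[corner[c]];
          if (val[c] > level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], out[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = TETS[t][c];
            if (val[cc] > level) in[nin++] = cc; else out[nout++] = cc;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int a = in[0];
            int v0 = vertexOnEdge(corner[a], corner[out[0]]);
            int v1 = vertexOnEdge(corner[a], corner[out[1]]);
            int v2 = vertexOnEdge(corner[a], corner[out[2]]);
            tris.push_back(v0); tris.push_back(v1); tris.push_back(v2);
          } else if (nin == 3) {
            int a = out[0];
            int v0 = vertexOnEdge(corner[in[0]], corner[a]);
            int v1 = vertexOnEdge(corner[in[1]], corner[a]);
            int v2 = vertexOnEdge(corner[in[2]], corner[a]);
            tris.push_back(v0); tris.push_back(v1); tris.push_back(v2);
          } else {  // 2-2: quad split into two triangles
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int vac = vertexOnEdge(corner[a], corner[c]);
            int vad = vertexOnEdge(corner[a], corner[d]);
            int vbc = vertexOnEdge(corner[b], corner[c]);
            int vbd = vertexOnEdge(corner[b], corner[d]);
            tris.push_back(vac); tris.push_back(vad); tris.push_back(vbd);
            tris.push_back(vac); tris.push_back(vbd); tris.push_back(vbc);
          }
        }
      }
    }
  }

  const int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v)
    for (int c = 0; c < 3; ++c) V(v, c) = verts[3 * (R_xlen_t)v + c];
  IntegerMatrix T(nt, 3);
  for (int r = 0; r < nt; ++r)
    for (int c = 0; c < 3; ++c) T(r, c) = tris[3 * (R_xlen_t)r + c];
  return List::create(Named("vertices") = V, Named("triangles") = T);
}

// Exact maximum pairwise Euclidean distance over the rows of `pts`,
// restricted to the (1-based) columns in `keepCols`.
// [[Rcpp::export(name = ".cppMaxPairwiseDist")]]
double cppMaxPairwiseDist(NumericMatrix pts, IntegerVector keepCols) {
  const int n = pts.nrow(), m = keepCols.size();
  std::vector<const double*> col(m);
  for (int c = 0; c < m; ++c) col[c] = &pts(0, keepCols[c] - 1);
  double best = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        double d = col[c][i] - col[c][j];
        s += d * d;
      }
      if (s > best) best = s;
    }
  }
  return std::sqrt(best);
}
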