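name,role,parents,file
A,target,,A.txt
B,context,,B.txt
C,context,,C.txt
D,context,,D.txt
E,context,,E.txt
F,context,,F.txt
G,context,,G.txt
H,target,,H.txt
I,context,,I.txt
J,context,,J.txt
K,context,,K.txt
L,context,,L.txt
M,context,,M.txt
N,context,,N.txt
O,target,,O.txt
P,target,,P.txt
Q,context,,Q.txt
R,target,,R.txt
S,context,,S.txt
T,context,,T.txt
U,target,,U.txt
V,context,,V.txt
W,context,,W.txt
X,context,,X.txt
Y,context,,Y.txt
Z,context,,Z.txt
AH,ambiguous,AH,AH.txt
OU,ambiguous,OU,OU.txt
PR,ambiguous,PR,PR.txt
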