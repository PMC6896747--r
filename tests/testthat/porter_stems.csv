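word,stem
abstracts,abstract
activate,activ
adjustable,adjust
adjustment,adjust
adoption,adopt
agreed,agre
agrees,agre
airliner,airlin
allowance,allow
an,an
analogousli,analog
apples,appl
application,applic
applied,appli
apply,appli
argument,argument
arguments,argument
as,as
assistance,assist
at,at
aucs,auc
author,author
away,awai
bagging,bag
between,between
bibr,bibr
biomedical,biomed
bled,bled
boolean,boolean
bowdlerize,bowdler
burden,burden
callousness,callous
caresses,caress
cats,cat
cease,ceas
characteristic,characterist
ci,ci
citations,citat
classification,classif
classifier,classifi
collected,collect
communism,commun
compare,compar
computational,comput
conditional,condit
conflated,conflat
connect,connect
connected,connect
connecting,connect
connection,connect
connections,connect
controll,control
controlled,control
cross,cross
data,data
decisiveness,decis
defensible,defens
dependent,depend
design,design
dies,di
differentiate,differenti
differentli,differ
digitizer,digit
documents,document
doi,doi
dried,dri
dying,dy
effective,effect
electrical,electr
electriciti,electr
entries,entri
failing,fail
falling,fall
feed,feed
feudalism,feudal
filing,file
fizzed,fizz
flies,fli
formaliti,formal
formalize,formal
formative,form
gains,gain
generalizations,gener
goodness,good
gov,gov
gyroscopic,gyroscop
hampers,hamper
happy,happi
held,held
hesitanci,hesit
hissing,hiss
homologous,homolog
hopeful,hope
hopefulness,hope
hopping,hop
hyper,hyper
imbalance,imbal
inference,infer
involved,involv
irritant,irrit
issues,issu
kernels,kernel
low,low
lv,lv
lying,ly
methods,method
might,might
mining,mine
misclassification,misclassif
model,model
motoring,motor
next,next
obtaining,obtain
operator,oper
oscillators,oscil
oversampling,oversampl
performed,perform
plastered,plaster
ponies,poni
poorly,poorli
predication,predic
probate,probat
provide,provid
pubmed,pubm
radicalli,radic
ran,ran
randomized,random
rate,rate
rational,ration
reached,reach
receiver,receiv
reduce,reduc
reduction,reduct
region,region
regularized,regular
relational,relat
remedy,remedi
replacement,replac
reports,report
rescale,rescal
rescaled,rescal
resulting,result
review,review
revival,reviv
roll,roll
screening,screen
selected,select
sensibiliti,sensibl
sensitiviti,sensit
show,show
shown,shown
sing,sing
situation,situat
sized,size
skies,ski
sky,sky
split,split
systematic,systemat
tanned,tan
technique,techniqu
technology,technologi
ties,ti
together,togeth
trials,trial
triplicate,triplic
troubled,troubl
undersampling,undersampl
valenci,valenc
vietnamization,vietnam
vileli,vile
word,word
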